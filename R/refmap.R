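# Mapping crystallised fragments onto the reference sequence.
#
# The validity conditions (subsequence embedding without indels, identity and
# e-value thresholds, pairwise overlap) reduce the alignment to a gapless
# offset scan of the fragment along the reference: the best placement is the
# one with the most matches, ties broken by the smallest offset.

#' Read a reference sequence from FASTA
#'
#' @param path FASTA file; the first record is used.
#' @return object of class `reference_sequence` with `id`, `sequence`,
#'   `length`.
#' @export
read_reference <- function(path) {
  ss <- Biostrings::readAAStringSet(path)
  if (length(ss) < 1) stop("no sequences in ", path)
  reference_sequence(names(ss)[1], as.character(ss[[1]]))
}

#' Construct a reference sequence
#' @param id accession carried verbatim into outputs.
#' @param sequence amino-acid string (20 letters + X).
#' @export
reference_sequence <- function(id, sequence) {
  sequence <- toupper(gsub("\\s", "", sequence))
  if (!nchar(sequence)) stop("empty reference sequence")
  if (grepl("[^ACDEFGHIKLMNPQRSTVWYX]", sequence)) {
    stop("reference sequence contains non-amino-acid letters")
  }
  structure(list(id = sub("\\s.*", "", id), sequence = sequence,
                 length = nchar(sequence)),
            class = "reference_sequence")
}

#' Karlin-Altschul e-value of a gapless placement
#'
#' `E = K * m * n * exp(-lambda * S)` with `S` the BLOSUM62 score of the
#' placed (ungapped, end-to-end) alignment, `m` the fragment length and `n`
#' the reference length. Constants are the standard ungapped BLOSUM62 values
#' in natural-log units (`lambda` = 0.318, `K` = 0.13).
#'
#' @param score BLOSUM62 alignment score.
#' @param frag_len,ref_len sequence lengths.
#' @return expectation value.
#' @export
evalue <- function(score, frag_len, ref_len) {
  KA_K * frag_len * ref_len * exp(-KA_LAMBDA * score)
}

.blosum_score <- function(a, b) {
  B <- .blosum62()
  a <- strsplit(a, "")[[1]]; b <- strsplit(b, "")[[1]]
  a[!a %in% rownames(B)] <- "X"
  b[!b %in% rownames(B)] <- "X"
  sum(B[cbind(a, b)])
}

# best placement allowing exactly one indel, used only to report "indel" as
# the failure reason; returns the best identity (%) over split placements
.best_one_gap_identity <- function(frag, ref, max_gap = 30L) {
  m <- nchar(frag); n <- nchar(ref)
  fv <- strsplit(frag, "")[[1]]; rv <- strsplit(ref, "")[[1]]
  best <- 0
  for (cut in seq_len(m - 1)) {
    a <- fv[seq_len(cut)]; b <- fv[(cut + 1):m]
    la <- length(a); lb <- length(b)
    for (g in seq_len(max_gap)) {
      # deletion in fragment: reference has g unmatched residues at the cut
      if (la + lb + g <= n) {
        for (off in 0:(n - la - lb - g)) {
          matches <- sum(a == rv[off + seq_len(la)]) +
            sum(b == rv[off + la + g + seq_len(lb)])
          best <- max(best, 100 * matches / m)
        }
      }
      # insertion in fragment: g fragment residues unmatched at the cut
      if (g < lb && la + lb - g <= n) {
        b2 <- b[(g + 1):lb]; lb2 <- length(b2)
        for (off in 0:(n - la - lb2)) {
          matches <- sum(a == rv[off + seq_len(la)]) +
            sum(b2 == rv[off + la + seq_len(lb2)])
          best <- max(best, 100 * matches / m)
        }
      }
    }
  }
  best
}

#' Place a fragment on the reference sequence
#'
#' Scans every gapless end-to-end placement of `frag` inside `ref`, scores
#' identity (matches / fragment length) and the Karlin-Altschul e-value of
#' the best placement, and checks the validity conditions: embeddable without
#' indels, identity >= `min_identity`, e-value < `max_evalue`. Ties on
#' identity go to the smallest offset (recorded in `reasons` as
#' `"ambiguous"`). The pairwise overlap condition is checked later, in
#' [build_residue_map()].
#'
#' @param frag amino-acid string (a SEQRES sequence).
#' @param ref a `reference_sequence`.
#' @param min_identity acceptance boundary in percent (default 95).
#' @param max_evalue e-value acceptance boundary (default 1e-3).
#' @return object of class `mapping_result`: `offset` (1-based start on the
#'   reference, NA if not embeddable), `identity` (%), `evalue`, `valid`,
#'   `reasons` (character vector of failed conditions).
#' @export
map_fragment <- function(frag, ref, min_identity = 95, max_evalue = 1e-3) {
  stopifnot(inherits(ref, "reference_sequence"))
  frag <- toupper(gsub("\\s", "", frag))
  m <- nchar(frag); n <- ref$length
  if (m < 1) stop("empty fragment")

  if (m > n) {
    return(structure(list(offset = NA_integer_, identity = 0,
                          evalue = Inf, valid = FALSE,
                          reasons = "not embeddable"),
                     class = "mapping_result"))
  }
  fv <- strsplit(frag, "")[[1]]
  rv <- strsplit(ref$sequence, "")[[1]]
  offsets <- seq_len(n - m + 1L)
  matches <- vapply(offsets, function(o) sum(fv == rv[o:(o + m - 1L)]),
                    numeric(1))
  best <- which.max(matches)          # which.max takes the first = smallest
  offset <- offsets[best]
  identity <- 100 * matches[best] / m
  score <- .blosum_score(frag,
                         substr(ref$sequence, offset, offset + m - 1L))
  ev <- evalue(score, m, n)

  reasons <- character(0)
  if (sum(matches == matches[best]) > 1) reasons <- c(reasons, "ambiguous")
  if (identity < min_identity) {
    reasons <- c(reasons, "identity")
    if (m >= 2 && .best_one_gap_identity(frag, ref$sequence) >= min_identity) {
      reasons <- c(reasons, "indel")
    }
  }
  if (ev >= max_evalue) reasons <- c(reasons, "evalue")
  valid <- !any(reasons %in% c("identity", "evalue", "not embeddable"))

  structure(list(offset = offset, identity = identity, evalue = ev,
                 valid = valid, reasons = reasons),
            class = "mapping_result")
}

#' Build the joint per-position residue map for a structure pair
#'
#' Places both SEQRES sequences on the reference and classifies every
#' reference position, per structure, as `observed` (coordinates present),
#' `disordered` (inside the mapped interval, in SEQRES, no coordinates) or
#' `null` (outside the crystallised fragment).
#'
#' @param s1,s2 `protein_structure` objects (after / before states in any
#'   order; the map is symmetric).
#' @param ref a `reference_sequence`.
#' @param min_identity,max_evalue validity thresholds, see [map_fragment()].
#' @return object of class `residue_map`: `ref`, `mapping1`, `mapping2`,
#'   `status1`, `status2` (character vectors of length L), `res_idx1`,
#'   `res_idx2` (SEQRES index of the residue at each reference position, NA
#'   where not observed), `s1`, `s2`, `overlap` (intersection interval).
#' @export
build_residue_map <- function(s1, s2, ref, min_identity = 95,
                              max_evalue = 1e-3) {
  m1 <- map_fragment(s1$seqres, ref, min_identity, max_evalue)
  m2 <- map_fragment(s2$seqres, ref, min_identity, max_evalue)
  if (!m1$valid) stop("structure 1 does not map validly: ",
                      paste(m1$reasons, collapse = ", "))
  if (!m2$valid) stop("structure 2 does not map validly: ",
                      paste(m2$reasons, collapse = ", "))

  L <- ref$length
  iv1 <- c(m1$offset, m1$offset + nchar(s1$seqres) - 1L)
  iv2 <- c(m2$offset, m2$offset + nchar(s2$seqres) - 1L)
  lo <- max(iv1[1], iv2[1]); hi <- min(iv1[2], iv2[2])
  if (lo > hi) stop("no overlap between the two mapped regions")

  status_of <- function(ps, iv) {
    st <- rep("null", L)
    inside <- seq(iv[1], iv[2])
    st[inside] <- "disordered"
    st[iv[1] - 1L + ps$observed_idx] <- "observed"
    st
  }
  res_idx_of <- function(ps, iv, st) {
    ri <- rep(NA_integer_, L)
    ri[iv[1] - 1L + ps$observed_idx] <- ps$observed_idx
    ri
  }
  st1 <- status_of(s1, iv1); st2 <- status_of(s2, iv2)

  structure(list(ref = ref, mapping1 = m1, mapping2 = m2,
                 status1 = st1, status2 = st2,
                 res_idx1 = res_idx_of(s1, iv1, st1),
                 res_idx2 = res_idx_of(s2, iv2, st2),
                 s1 = s1, s2 = s2, overlap = c(lo, hi)),
            class = "residue_map")
}

#' C-alpha coordinates of both structures on the reference ruler
#' @param map a `residue_map`.
#' @return list of two L x 3 matrices (`ca1`, `ca2`) with NA rows where a
#'   position is not observed in that structure.
#' @export
ref_ca_matrices <- function(map) {
  L <- map$ref$length
  place <- function(ps, res_idx) {
    ca <- ca_matrix(ps)
    m <- matrix(NA_real_, L, 3)
    obs <- which(!is.na(res_idx))
    m[obs, ] <- ca[res_idx[obs], , drop = FALSE]
    m
  }
  list(ca1 = place(map$s1, map$res_idx1), ca2 = place(map$s2, map$res_idx2))
}
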