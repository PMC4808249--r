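# Sequence-derived tracks: entropy conservation over a user-supplied MSA with
# independent-count sequence weighting, and the windowed Kyte-Doolittle
# hydropathy sum.

#' Read an aligned FASTA file as an MSA
#'
#' The reference row is located by id match against `ref$id`, falling back to
#' the row whose degapped sequence equals the reference sequence.
#'
#' @param path aligned FASTA (all rows equal length, gaps `-`).
#' @param ref a `reference_sequence`.
#' @return object of class `msa`: `rows` (character matrix, sequences x
#'   columns), `ids`, `ref_row`, `col_to_ref` (reference position per column,
#'   NA at reference gaps).
#' @export
read_msa <- function(path, ref) {
  ss <- Biostrings::readAAStringSet(path)
  if (!length(ss)) stop("no sequences in ", path)
  seqs <- toupper(as.character(ss))
  widths <- nchar(seqs)
  if (length(unique(widths)) != 1) stop("MSA rows differ in length")
  ids <- sub("\\s.*", "", names(ss))
  rows <- do.call(rbind, strsplit(seqs, ""))
  msa_from_matrix(rows, ids, ref)
}

#' Build an MSA object from a character matrix
#' @param rows sequences x columns character matrix (gaps `-`).
#' @param ids row ids.
#' @param ref a `reference_sequence`.
#' @export
msa_from_matrix <- function(rows, ids, ref) {
  ref_row <- match(ref$id, ids)
  if (is.na(ref_row)) {
    degap <- apply(rows, 1, function(r) paste(r[r != "-"], collapse = ""))
    ref_row <- match(ref$sequence, degap)
  }
  if (is.na(ref_row)) stop("reference row not found in MSA")
  rr <- rows[ref_row, ]
  degapped <- paste(rr[rr != "-"], collapse = "")
  if (degapped != ref$sequence) {
    stop("degapped reference row does not equal the reference sequence")
  }
  col_to_ref <- rep(NA_integer_, ncol(rows))
  col_to_ref[rr != "-"] <- seq_len(sum(rr != "-"))
  structure(list(rows = rows, ids = ids, ref_row = ref_row,
                 col_to_ref = col_to_ref, ref = ref),
            class = "msa")
}

# pairwise fractional identity between two aligned rows: matches over columns
# where at least one row is non-gap
.row_identity <- function(a, b) {
  any_res <- a != "-" | b != "-"
  if (!any(any_res)) return(0)
  sum(a == b & a != "-") / sum(any_res)
}

.single_linkage_clusters <- function(rows, idx, theta) {
  k <- length(idx)
  if (k <= 1) return(k)
  parent <- seq_len(k)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  for (a in seq_len(k - 1)) for (b in (a + 1):k) {
    if (.row_identity(rows[idx[a], ], rows[idx[b], ]) >= theta) {
      ra <- find(a); rb <- find(b)
      if (ra != rb) parent[ra] <- rb
    }
  }
  length(unique(vapply(seq_len(k), find, integer(1))))
}

#' Independent-count weighted frequencies of one alignment column
#'
#' For each amino-acid type present at the column, the rows carrying it are
#' single-linkage clustered at fractional identity `theta` over the full
#' rows; the independent count of the type is the number of clusters, and
#' frequencies are independent counts renormalised over types. Near-identical
#' homologs thus count once. With `theta > 1` every row is its own cluster
#' and the frequencies reduce to raw frequencies.
#'
#' @param msa an `msa` object.
#' @param column column index.
#' @param theta clustering identity threshold (default 0.8).
#' @return named numeric vector of frequencies (NULL for an all-gap column).
#' @export
independent_count_weights <- function(msa, column, theta = 0.8) {
  col <- msa$rows[, column]
  res <- which(col != "-" & col != "." & col != "X")
  if (!length(res)) return(NULL)
  types <- unique(col[res])
  ic <- vapply(types, function(a) {
    carriers <- res[col[res] == a]
    if (theta > 1) length(carriers)
    else .single_linkage_clusters(msa$rows, carriers, theta)
  }, numeric(1))
  ic / sum(ic)
}

#' Entropy conservation score of a frequency vector
#'
#' `raw = sum(f * ln f)` lies in `[-ln 20, 0]` (about -2.996 at the uniform
#' 20-type column, 0 at a single-type column); the normalised score maps that
#' linearly to `[0, 1]`, 1 = fully conserved.
#'
#' @param freqs named frequency vector summing to 1.
#' @return list `raw`, `normalized`.
#' @export
conservation_score <- function(freqs) {
  if (is.null(freqs) || !length(freqs)) {
    return(list(raw = NA_real_, normalized = NA_real_))
  }
  f <- freqs[freqs > 0]
  raw <- sum(f * log(f))
  list(raw = raw, normalized = (raw + log(20)) / log(20))
}

#' Conservation profile on the reference ruler
#'
#' @param msa an `msa` object.
#' @param theta clustering threshold for [independent_count_weights()]; pass
#'   a value > 1 for unweighted frequencies.
#' @return a profile track of normalised conservation in `[0, 1]` (NA at
#'   all-gap columns).
#' @export
conservation_profile <- function(msa, theta = 0.8) {
  L <- msa$ref$length
  vals <- rep(NA_real_, L)
  for (col in which(!is.na(msa$col_to_ref))) {
    f <- independent_count_weights(msa, col, theta)
    vals[msa$col_to_ref[col]] <- conservation_score(f)$normalized
  }
  new_profile(msa$ref$id, vals, kind = "conservation")
}

#' Windowed hydropathy-sum profile
#'
#' Value at position `i` is the sum of Kyte-Doolittle scale values over the
#' `window` residues centred at `i` (7 on each side by default), truncated at
#' the termini. `X` contributes nothing.
#'
#' @param ref a `reference_sequence` (or plain amino-acid string).
#' @param window window width, odd (default 15).
#' @return a profile track (dimensionless scale units).
#' @export
hydropathy_profile <- function(ref, window = 15L) {
  seqchr <- if (inherits(ref, "reference_sequence")) ref$sequence else ref
  id <- if (inherits(ref, "reference_sequence")) ref$id else "seq"
  stopifnot(window %% 2 == 1, window >= 1)
  hw <- (window - 1L) %/% 2L
  aa <- strsplit(toupper(seqchr), "")[[1]]
  per <- unname(KYTE_DOOLITTLE[aa])
  per[is.na(per)] <- 0
  L <- length(per)
  vals <- vapply(seq_len(L), function(i)
    sum(per[max(1L, i - hw):min(L, i + hw)]), numeric(1))
  new_profile(id, vals, kind = "hydropathy")
}
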