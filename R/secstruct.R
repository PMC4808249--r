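# Kabsch-Sander secondary-structure assignment, 8 -> 3 class merging, and the
# disorder (D) / null (N) overlay on the reference ruler.
#
# The assigner follows the classic dictionary: the amide hydrogen is placed
# geometrically from the previous peptide C=O, hydrogen bonds are scored with
# the electrostatic model E = 0.084*332*(1/rON + 1/rCH - 1/rOH - 1/rCN) and
# assigned below -0.5 kcal/mol, n-turns (n = 3,4,5) require two consecutive
# turn patterns to seed a helix, bridge patterns seed strands/isolated
# bridges, and the bend class uses the 70 degree kappa threshold. Chain
# breaks (consecutive-residue Ca-Ca > 4.5 A, or a gap in SEQRES numbering)
# terminate all patterns.

.backbone_of <- function(res) {
  out <- list(N = NULL, CA = NULL, C = NULL, O = NULL)
  for (a in res$atoms) if (a$name %in% names(out) && is.null(out[[a$name]])) {
    out[[a$name]] <- a$coords
  }
  out
}

.vnorm <- function(v) sqrt(sum(v^2))

#' Assign 8-class secondary structure
#'
#' Runs the hydrogen-bond/geometry dictionary on the observed residues of a
#' chain and returns one of G/H/I/E/B/T/S/C per SEQRES position (NA where no
#' coordinates). Residues missing backbone atoms are assigned C with a
#' warning.
#'
#' @param ps a `protein_structure`.
#' @return character vector of length `nchar(seqres)`.
#' @export
assign_8class <- function(ps) {
  L <- nchar(ps$seqres)
  raw <- rep(NA_character_, L)
  obs <- ps$observed_idx
  n <- length(obs)
  if (n == 0) return(raw)

  bb <- lapply(obs, function(i) .backbone_of(ps$observed[[i]]))
  complete <- vapply(bb, function(b)
    !any(vapply(b, is.null, logical(1))), logical(1))
  if (any(!complete)) {
    warning(sum(!complete), " residue(s) missing backbone atoms; assigned C")
  }
  is_pro <- vapply(obs, function(i) ps$observed[[i]]$name3 == "PRO",
                   logical(1))

  # connectivity between consecutive observed residues (index k -> k+1)
  connected <- rep(FALSE, n - 1)
  if (n > 1) for (k in seq_len(n - 1)) {
    if (obs[k + 1] != obs[k] + 1L) next
    if (!complete[k] || !complete[k + 1]) next
    connected[k] <- .vnorm(bb[[k + 1]]$CA - bb[[k]]$CA) <= DSSP_CHAIN_BREAK
  }
  contiguous <- function(a, b) {   # residues a..b form an unbroken run
    a <- max(1L, a); if (b > n || a >= b) return(a <= b && a >= 1 && b <= n)
    all(connected[a:(b - 1L)])
  }

  # amide H placement from previous C=O
  Hpos <- vector("list", n)
  for (k in seq_len(n)) {
    if (k == 1 || is_pro[k] || !complete[k]) next
    if (!connected[k - 1]) next
    co <- bb[[k - 1]]$C - bb[[k - 1]]$O
    Hpos[[k]] <- bb[[k]]$N + co / .vnorm(co)
  }

  # hydrogen bonds: HB[a, d] TRUE when N-H of residue d donates to C=O of a
  HB <- matrix(FALSE, n, n)
  for (d in seq_len(n)) {
    if (is.null(Hpos[[d]])) next
    Nd <- bb[[d]]$N; Hd <- Hpos[[d]]
    for (a in seq_len(n)) {
      if (a == d || a == d - 1L) next
      if (!complete[a]) next
      if (.vnorm(bb[[a]]$CA - bb[[d]]$CA) > 9) next
      Ca <- bb[[a]]$C; Oa <- bb[[a]]$O
      E <- DSSP_Q * (1 / .vnorm(Oa - Nd) + 1 / .vnorm(Ca - Hd) -
                     1 / .vnorm(Oa - Hd) - 1 / .vnorm(Ca - Nd))
      HB[a, d] <- E < DSSP_HBOND_CUTOFF
    }
  }

  # n-turns: turn_n[i] when C=O of i accepts from N-H of i+n within one run
  turn <- list()
  for (tn in 3:5) {
    tt <- rep(FALSE, n)
    for (i in seq_len(n - tn)) {
      if (contiguous(i, i + tn) && HB[i, i + tn]) tt[i] <- TRUE
    }
    turn[[as.character(tn)]] <- tt
  }

  helix <- list()   # per n: logical flags over residues
  for (tn in 3:5) {
    tt <- turn[[as.character(tn)]]
    hh <- rep(FALSE, n)
    for (i in 2:max(2, n)) {
      if (i <= n - tn + 1 && i >= 2 && tt[i - 1] && tt[i]) {
        hh[i:(i + tn - 1L)] <- TRUE
      }
    }
    helix[[as.character(tn)]] <- hh
  }

  # bridges
  bridge_type <- matrix("", n, n)   # "P" / "A"
  if (n >= 4) for (i in seq_len(n)) for (j in seq_len(n)) {
    if (j < i + 3L) next
    if (!complete[i] || !complete[j]) next
    par <- (i > 1 && i < n && HB[i - 1, j] && HB[j, i + 1]) ||
           (j > 1 && j < n && HB[j - 1, i] && HB[i, j + 1])
    anti <- (HB[i, j] && HB[j, i]) ||
            (i > 1 && j < n && i < n && j > 1 &&
             HB[i - 1, j + 1] && HB[j - 1, i + 1])
    if (par && contiguous(i - 1, i + 1) && contiguous(j - 1, j + 1)) {
      bridge_type[i, j] <- bridge_type[j, i] <- "P"
    } else if (anti) {
      bridge_type[i, j] <- bridge_type[j, i] <- "A"
    }
  }
  in_bridge <- apply(bridge_type != "", 1, any)
  in_ladder <- rep(FALSE, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    ty <- bridge_type[i, j]
    if (ty == "") next
    ext <- FALSE
    for (di in c(-1L, 1L)) for (dj in c(-1L, 1L)) {
      i2 <- i + di; j2 <- j + dj
      if (i2 >= 1 && i2 <= n && j2 >= 1 && j2 <= n &&
          bridge_type[i2, j2] == ty) ext <- TRUE
    }
    if (ext) in_ladder[i] <- in_ladder[j] <- TRUE
  }

  # turn class T: residues bracketed by an n-turn
  is_T <- rep(FALSE, n)
  for (tn in 3:5) {
    tt <- turn[[as.character(tn)]]
    for (i in which(tt)) {
      is_T[(i + 1L):(i + tn - 1L)] <- TRUE
    }
  }

  # bend S: kappa > 70 degrees
  is_S <- rep(FALSE, n)
  if (n >= 5) for (k in 3:(n - 2)) {
    if (!contiguous(k - 2, k + 2)) next
    u <- bb[[k]]$CA - bb[[k - 2]]$CA
    v <- bb[[k + 2]]$CA - bb[[k]]$CA
    kappa <- acos(max(-1, min(1, sum(u * v) / (.vnorm(u) * .vnorm(v))))) *
      180 / pi
    is_S[k] <- kappa > DSSP_BEND_KAPPA
  }

  # priority: H > E > G > I > T > S, then B, else C
  cls <- rep("C", n)
  cls[is_S] <- "S"
  cls[is_T] <- "T"
  cls[helix[["5"]]] <- "I"
  cls[helix[["3"]]] <- "G"
  cls[in_bridge & !in_ladder] <- "B"
  cls[in_ladder] <- "E"
  cls[helix[["4"]]] <- "H"
  cls[!complete] <- "C"

  raw[obs] <- cls
  raw
}

#' Merge 8-class secondary structure to 3 classes
#'
#' G and I join H; T, B and S join C; E stays E.
#'
#' @param raw character vector over \{G,H,I,E,B,T,S,C\} (NA passed through).
#' @return character vector over \{H,E,C\}.
#' @export
merge_3class <- function(raw) {
  out <- rep(NA_character_, length(raw))
  known <- !is.na(raw)
  bad <- known & !(raw %in% c("G", "H", "I", "E", "B", "T", "S", "C"))
  if (any(bad)) stop("unknown secondary-structure symbol: ",
                     paste(unique(raw[bad]), collapse = ", "))
  out[known & raw %in% c("G", "H", "I")] <- "H"
  out[known & raw == "E"] <- "E"
  out[known & raw %in% c("T", "B", "S", "C")] <- "C"
  out
}

#' Overlay disorder and null classes on the reference ruler
#'
#' Produces the 5-class profile \{H,E,C,D,N\}: `N` outside the structure's
#' mapped interval (in the reference but not in SEQRES), `D` where the
#' SEQRES residue has no coordinates, and the merged 3-class elsewhere. D and
#' N depend only on the residue map, never on geometry.
#'
#' @param map a `residue_map`.
#' @param state `1` (after/bound) or `2` (before/free).
#' @param merged optional pre-computed 3-class vector on SEQRES positions;
#'   computed from the internal assigner when missing.
#' @return a profile track over \{H,E,C,D,N\}.
#' @export
overlay_disorder <- function(map, state = 1, merged = NULL) {
  ps <- if (state == 1) map$s1 else map$s2
  status <- if (state == 1) map$status1 else map$status2
  res_idx <- if (state == 1) map$res_idx1 else map$res_idx2
  if (is.null(merged)) merged <- merge_3class(assign_8class(ps))
  L <- map$ref$length
  vals <- rep("N", L)
  vals[status == "disordered"] <- "D"
  obs <- which(status == "observed")
  vals[obs] <- merged[res_idx[obs]]
  vals[is.na(vals)] <- "C"
  new_profile(map$ref$id, vals, kind = "secondary_structure")
}

#' Percentage of loop/coil among ordered residues
#'
#' @param profile a 5-class profile track (or plain character vector).
#' @return `100 * |C| / (|H| + |E| + |C|)`, or NA when no ordered positions.
#' @export
loop_fraction <- function(profile) {
  v <- if (inherits(profile, "ccprofile_track")) profile$values else profile
  ordered <- sum(v %in% c("H", "E", "C"))
  if (ordered == 0) return(NA_real_)
  100 * sum(v == "C", na.rm = TRUE) / ordered
}

#' Read a classic .dssp assignment file
#'
#' Parses the per-residue block of the classic text format (the line starting
#' `  #  RESIDUE AA` introduces it; the structure symbol sits in column 17)
#' and returns the raw 8-class track keyed by residue number, with blank
#' symbols mapped to C. Use as an external alternative to [assign_8class()].
#'
#' @param path .dssp file.
#' @param chain chain id to extract.
#' @return data.frame with `resnum`, `aa`, `ss8`.
#' @export
read_dssp <- function(path, chain = NULL) {
  lines <- readLines(path, warn = FALSE)
  start <- grep("^  #  RESIDUE", lines)
  if (!length(start)) stop("not a classic .dssp file: ", path)
  body <- lines[(start[1] + 1L):length(lines)]
  body <- body[nchar(body) >= 17]
  ch <- substr(body, 12, 12)
  aa <- substr(body, 14, 14)
  keep <- aa != "!"
  if (!is.null(chain)) keep <- keep & ch == chain
  body <- body[keep]
  ss <- substr(body, 17, 17)
  ss[ss == " "] <- "C"
  data.frame(resnum = as.integer(substr(body, 6, 10)),
             aa = substr(body, 14, 14),
             ss8 = ss, stringsAsFactors = FALSE)
}
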