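# The conformational change profile: a 21-residue window slides along the
# reference sequence; at each position the C-alpha coordinates of the
# residues observed in BOTH structures are rigidly superposed and the
# unweighted RMSD becomes the profile value. Positions not observed in both
# structures, and windows with too few common residues, are null.

#' CCP configuration
#'
#' @param half_window residues on each side of the current position; the
#'   window is `2 * half_window + 1` wide (default 10, i.e. 21 residues).
#' @param min_common minimum doubly observed residues a window needs before a
#'   superposition is attempted (default 3, the rigid-fit minimum).
#' @param estimator `"reweighted"` (default) or `"least_squares"`.
#' @return a `ccp_config` list.
#' @export
ccp_config <- function(half_window = 10L, min_common = 3L,
                       estimator = c("reweighted", "least_squares")) {
  estimator <- match.arg(estimator)
  stopifnot(half_window >= 1, min_common >= 3)
  structure(list(half_window = as.integer(half_window),
                 min_common = as.integer(min_common), estimator = estimator),
            class = "ccp_config")
}

#' Construct a per-position profile track
#' @param ref_id reference accession.
#' @param values vector of length L (NA = null).
#' @param kind free-text tag; `units` optional.
#' @export
new_profile <- function(ref_id, values, kind, units = NULL) {
  structure(list(ref_id = ref_id, length = length(values), values = values,
                 kind = kind, units = units),
            class = "ccprofile_track")
}

#' Compute the conformational change profile
#'
#' @param map a `residue_map` from [build_residue_map()].
#' @param config a [ccp_config()].
#' @return a profile track of local RMSDs (Angstrom); NA where the position
#'   itself is not observed in both structures or where the window holds
#'   fewer than `min_common` doubly observed residues. Terminal windows are
#'   truncated, never wrapped.
#' @export
compute_ccp <- function(map, config = ccp_config()) {
  stopifnot(inherits(map, "residue_map"))
  cas <- ref_ca_matrices(map)
  L <- map$ref$length
  both <- !is.na(cas$ca1[, 1]) & !is.na(cas$ca2[, 1])
  hw <- config$half_window
  vals <- rep(NA_real_, L)
  for (i in which(both)) {
    win <- max(1L, i - hw):min(L, i + hw)
    common <- win[both[win]]
    if (length(common) < config$min_common) next
    vals[i] <- superpose_rmsd(cas$ca1[common, , drop = FALSE],
                              cas$ca2[common, , drop = FALSE],
                              estimator = config$estimator)
  }
  new_profile(map$ref$id, vals, kind = "ccp", units = "Angstrom")
}

#' Global RMSD of a structure pair
#'
#' One superposition over every reference position observed in both
#' structures.
#'
#' @inheritParams compute_ccp
#' @return unweighted RMSD in Angstrom.
#' @export
global_rmsd <- function(map, config = ccp_config()) {
  cas <- ref_ca_matrices(map)
  both <- !is.na(cas$ca1[, 1]) & !is.na(cas$ca2[, 1])
  if (sum(both) < 3) stop("fewer than 3 residues observed in both structures")
  superpose_rmsd(cas$ca1[both, , drop = FALSE],
                 cas$ca2[both, , drop = FALSE],
                 estimator = config$estimator)
}

#' Superposition transform aligning the after structure onto the before frame
#'
#' Fits the doubly observed C-alpha set and returns the full superposition
#' object, for writing a two-model superposed PDB file.
#'
#' @inheritParams compute_ccp
#' @return a `superposition` (rotation/translation map `s1` onto `s2`).
#' @export
global_superposition <- function(map, config = ccp_config()) {
  cas <- ref_ca_matrices(map)
  both <- !is.na(cas$ca1[, 1]) & !is.na(cas$ca2[, 1])
  if (sum(both) < 3) stop("fewer than 3 residues observed in both structures")
  X <- cas$ca2[both, , drop = FALSE]   # before frame is the target
  Y <- cas$ca1[both, , drop = FALSE]
  if (config$estimator == "least_squares") kabsch(X, Y) else ml_superpose(X, Y)
}
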