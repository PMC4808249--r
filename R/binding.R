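# Potential binding-target-site profile: a reference position is flagged when
# any heavy atom of the residue (in the bound-state structure) lies within
# the site cutoff of any heavy atom of a binding target. Target names are
# associated at the tighter name cutoff.

.target_heavy_coords <- function(target) {
  res_list <- if (!is.null(target$residues)) target$residues
    else if (inherits(target$source, "protein_structure")) {
      ps <- target$source
      lapply(ps$observed_idx, function(i) ps$observed[[i]])
    } else list(target$source)
  coords <- do.call(rbind, lapply(res_list, function(r) {
    ha <- heavy_atoms(r)
    if (!length(ha)) return(NULL)
    do.call(rbind, lapply(ha, function(a) a$coords))
  }))
  coords
}

.min_dist_to_targets <- function(res, target_coords) {
  ha <- heavy_atoms(res)
  if (!length(ha) || is.null(target_coords)) return(Inf)
  rc <- do.call(rbind, lapply(ha, function(a) a$coords))
  # pairwise squared distances, residue atoms x target atoms
  d2 <- outer(rowSums(rc^2), rowSums(target_coords^2), "+") -
    2 * rc %*% t(target_coords)
  sqrt(max(0, min(d2)))
}

#' Boolean potential binding-target-site profile
#'
#' Position `i` is `TRUE` when any heavy atom of the residue observed at `i`
#' in the bound structure is within `cutoff` of at least one heavy atom of a
#' binding target, `FALSE` otherwise, and `NA` where the bound structure has
#' no observed residue.
#'
#' @param map a `residue_map` whose `s1` is the bound-state structure.
#' @param targets list of binding targets (see [extract_binding_targets()]);
#'   waters and pseudo-ligands must already be excluded.
#' @param cutoff contact distance in Angstrom (default 5).
#' @return a logical profile track.
#' @export
binding_site_profile <- function(map, targets, cutoff = 5.0) {
  L <- map$ref$length
  vals <- rep(NA, L)
  obs <- which(!is.na(map$res_idx1))
  vals[obs] <- FALSE
  coords <- lapply(targets, .target_heavy_coords)
  for (i in obs) {
    res <- map$s1$observed[[map$res_idx1[i]]]
    for (tc in coords) {
      if (.min_dist_to_targets(res, tc) <= cutoff) { vals[i] <- TRUE; break }
    }
  }
  new_profile(map$ref$id, vals, kind = "binding_site")
}

#' Per-position binding-target name association
#'
#' Names of targets with any heavy atom within `cutoff` (default 3 Angstrom)
#' of a residue's heavy atoms, deduplicated and sorted.
#'
#' @inheritParams binding_site_profile
#' @return a profile track whose values are semicolon-joined names ("" where
#'   no target is close, NA where unobserved).
#' @export
associate_names <- function(map, targets, cutoff = 3.0) {
  L <- map$ref$length
  vals <- rep(NA_character_, L)
  obs <- which(!is.na(map$res_idx1))
  vals[obs] <- ""
  coords <- lapply(targets, .target_heavy_coords)
  nms <- vapply(targets, function(t) t$name, character(1))
  for (i in obs) {
    res <- map$s1$observed[[map$res_idx1[i]]]
    close <- vapply(seq_along(targets), function(k)
      .min_dist_to_targets(res, coords[[k]]) <= cutoff, logical(1))
    if (any(close)) vals[i] <- paste(sort(unique(nms[close])), collapse = ";")
  }
  new_profile(map$ref$id, vals, kind = "binding_names")
}
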