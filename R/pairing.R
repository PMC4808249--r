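# Before/after pair enumeration. A pair (s2 before, s1 after) is valid when
# the two chains live in different files, both map onto the reference with
# overlapping intervals, and the after-file contains every molecule of the
# before-file plus at least one extra. Extras within the site cutoff of the
# paired chain become the binding targets.

#' Is a component id excluded from binding-target consideration?
#'
#' Waters and pseudo-ligands (crystallisation artifacts such as
#' selenomethionine or heavy-metal soaking ions) are never binding targets
#' and never count in the molecular inventory.
#'
#' @param component_id 1-3 character het component id.
#' @param pseudo_ligands the excluded id set (defaults to the built-in list).
#' @return logical.
#' @export
is_excluded <- function(component_id, pseudo_ligands = PSEUDO_LIGAND_IDS) {
  toupper(component_id) %in% c(WATER_IDS, toupper(pseudo_ligands))
}

.file_inventory <- function(sf, exempt_chain = NULL,
                            pseudo_ligands = PSEUDO_LIGAND_IDS) {
  prot <- vapply(sf$protein_chains, function(pc) pc$seqres, character(1))
  if (!is.null(exempt_chain)) {
    drop <- match(sf$protein_chains[[exempt_chain]]$seqres, prot)
    if (!is.na(drop)) prot <- prot[-drop]
  }
  nuc <- vapply(sf$nucleic_chains, function(nc)
    paste(nc$seqres3 %||% vapply(nc$residues, function(r) r$name3,
                                 character(1)), collapse = " "), character(1))
  hets <- sf$het_groups$comp_id
  hets <- hets[!is_excluded(hets, pseudo_ligands)]
  list(prot = sort(unname(prot)), nuc = sort(unname(nuc)),
       het = sort(toupper(hets)))
}

.multiset_diff <- function(a, b) {
  # elements of a not covered by b, with multiplicity
  for (x in b) {
    k <- match(x, a)
    if (!is.na(k)) a <- a[-k]
  }
  a
}

#' Inventory superset test between two structure files
#'
#' `TRUE` iff every molecule of `F2` (polymer chains matched by exact SEQRES
#' string, het groups by component-id multiset; waters and pseudo-ligands
#' ignored) is present in `F1` and `F1` holds at least one extra
#' non-excluded molecule. The paired protein chains may be exempted from the
#' identity requirement (they are the pivot of the comparison).
#'
#' @param F1,F2 `structure_file` objects (after / before).
#' @param exempt_chain1,exempt_chain2 chain ids of the pivot chains.
#' @param pseudo_ligands excluded component ids.
#' @return list `ok` (logical) and `extras` (list with `prot`, `nuc`, `het`
#'   character vectors of extra molecules in `F1`).
#' @export
inventory_superset <- function(F1, F2, exempt_chain1 = NULL,
                               exempt_chain2 = NULL,
                               pseudo_ligands = PSEUDO_LIGAND_IDS) {
  inv1 <- .file_inventory(F1, exempt_chain1, pseudo_ligands)
  inv2 <- .file_inventory(F2, exempt_chain2, pseudo_ligands)
  missing <- c(.multiset_diff(inv2$prot, inv1$prot),
               .multiset_diff(inv2$nuc, inv1$nuc),
               .multiset_diff(inv2$het, inv1$het))
  extras <- list(prot = .multiset_diff(inv1$prot, inv2$prot),
                 nuc = .multiset_diff(inv1$nuc, inv2$nuc),
                 het = .multiset_diff(inv1$het, inv2$het))
  ok <- length(missing) == 0 && sum(lengths(extras)) >= 1
  list(ok = ok, extras = extras)
}

#' Categorise a binding target
#'
#' @param target a target object from [extract_binding_targets()].
#' @param ion_ids curated polyatomic ion component ids.
#' @return one of `"protein"`, `"nucleic acid"`, `"ligand"`, `"ion"`.
#' @export
categorize_target <- function(target, ion_ids = ION_IDS) {
  if (target$kind == "protein") return("protein")
  if (target$kind == "nucleic") return("nucleic acid")
  n_heavy <- max(vapply(target$residues, function(r)
    length(heavy_atoms(r)), integer(1)))
  if (n_heavy <= 1 || toupper(target$name) %in% toupper(ion_ids)) "ion"
  else "ligand"
}

#' Extract binding targets of a pair
#'
#' The extra molecules of the after-file (relative to the before-file) whose
#' heavy atoms come within `cutoff` of a heavy atom of the paired chain.
#'
#' @param after_file,before_file `structure_file` objects.
#' @param after_chain chain id of the paired (bound) chain in `after_file`.
#' @param before_chain chain id of the paired chain in `before_file`.
#' @param cutoff proximity in Angstrom (default 5).
#' @param pseudo_ligands excluded component ids.
#' @return list of targets, each `name` / `kind` / `category` / `residues`.
#' @export
extract_binding_targets <- function(after_file, before_file, after_chain,
                                    before_chain, cutoff = 5.0,
                                    pseudo_ligands = PSEUDO_LIGAND_IDS) {
  inv <- inventory_superset(after_file, before_file, after_chain,
                            before_chain, pseudo_ligands)
  pivot <- after_file$protein_chains[[after_chain]]
  pivot_coords <- .target_heavy_coords(
    list(residues = lapply(pivot$observed_idx,
                           function(i) pivot$observed[[i]])))
  near_pivot <- function(res_list) {
    tc <- .target_heavy_coords(list(residues = res_list))
    if (is.null(tc) || is.null(pivot_coords)) return(FALSE)
    d2 <- outer(rowSums(tc^2), rowSums(pivot_coords^2), "+") -
      2 * tc %*% t(pivot_coords)
    min(d2) <= cutoff^2
  }

  targets <- list()
  # extra protein chains: pick, per extra SEQRES string, a chain carrying it
  used <- character(0)
  for (sq in inv$extras$prot) {
    for (ch in names(after_file$protein_chains)) {
      pc <- after_file$protein_chains[[ch]]
      if (ch != after_chain && !(ch %in% used) && pc$seqres == sq) {
        res_list <- lapply(pc$observed_idx, function(i) pc$observed[[i]])
        if (near_pivot(res_list)) {
          targets <- c(targets, list(list(name = ch, kind = "protein",
                                          residues = res_list)))
        }
        used <- c(used, ch)
        break
      }
    }
  }
  for (sq in inv$extras$nuc) {
    for (ch in names(after_file$nucleic_chains)) {
      nc <- after_file$nucleic_chains[[ch]]
      key <- paste(nc$seqres3 %||% vapply(nc$residues, function(r) r$name3,
                                          character(1)), collapse = " ")
      if (!(ch %in% used) && key == sq) {
        if (near_pivot(nc$residues)) {
          targets <- c(targets, list(list(name = ch, kind = "nucleic",
                                          residues = nc$residues)))
        }
        used <- c(used, ch)
        break
      }
    }
  }
  # extra het groups: instances in file order beyond the before-file count
  het_ids <- vapply(after_file$het_residues, function(r) toupper(r$name3),
                    character(1))
  extra_het <- inv$extras$het
  taken <- integer(0)
  for (cid in unique(extra_het)) {
    n_extra <- sum(extra_het == cid)
    inst <- which(het_ids == cid)
    inst <- utils::tail(inst, n_extra)
    res_list <- after_file$het_residues[inst]
    if (near_pivot(res_list)) {
      targets <- c(targets, list(list(name = cid, kind = "het",
                                      residues = res_list)))
    }
  }
  for (k in seq_along(targets)) {
    targets[[k]]$category <- categorize_target(targets[[k]])
  }
  targets
}

#' Enumerate valid before/after structure pairs
#'
#' Scans every ordered pair of distinct files and every chain pair, keeping
#' those where both chains map validly onto the reference with overlapping
#' intervals and the after-file inventory strictly contains the before-file
#' inventory.
#'
#' @param files list of `structure_file` objects.
#' @param ref a `reference_sequence`.
#' @param min_identity,max_evalue mapping thresholds.
#' @return list of pair candidates: `before`, `after` (`protein_structure`),
#'   `before_file`, `after_file`, `targets`.
#' @export
find_pairs <- function(files, ref, min_identity = 95, max_evalue = 1e-3) {
  stopifnot(length(files) >= 2)
  pairs <- list()
  nf <- length(files)
  for (ia in seq_len(nf)) for (ib in seq_len(nf)) {
    if (ia == ib) next
    Fa <- files[[ia]]; Fb <- files[[ib]]
    if (Fa$id == Fb$id) next
    for (ca in names(Fa$protein_chains)) for (cb in names(Fb$protein_chains)) {
      sa <- Fa$protein_chains[[ca]]; sb <- Fb$protein_chains[[cb]]
      ma <- map_fragment(sa$seqres, ref, min_identity, max_evalue)
      mb <- map_fragment(sb$seqres, ref, min_identity, max_evalue)
      if (!ma$valid || !mb$valid) next
      lo <- max(ma$offset, mb$offset)
      hi <- min(ma$offset + nchar(sa$seqres), mb$offset + nchar(sb$seqres)) - 1L
      if (lo > hi) next
      inv <- inventory_superset(Fa, Fb, ca, cb)
      if (!inv$ok) next
      targets <- extract_binding_targets(Fa, Fb, ca, cb)
      pairs <- c(pairs, list(list(before = sb, after = sa,
                                  before_file = Fb, after_file = Fa,
                                  targets = targets)))
    }
  }
  pairs
}

#' Write the pair report TSV
#'
#' One row per pair: ids, chains, global RMSD, the worse (larger) of the two
#' resolutions and the semicolon-joined binding-target names.
#'
#' @param pairs result of [find_pairs()].
#' @param ref a `reference_sequence`.
#' @param path output TSV path.
#' @param config a [ccp_config()].
#' @return the report data.frame, invisibly.
#' @export
write_pair_report <- function(pairs, ref, path, config = ccp_config()) {
  rows <- lapply(pairs, function(p) {
    map <- build_residue_map(p$after, p$before, ref)
    res <- c(p$before_file$metadata$resolution, p$after_file$metadata$resolution)
    data.frame(
      before_id = p$before_file$id, before_chain = p$before$chain_id,
      after_id = p$after_file$id, after_chain = p$after$chain_id,
      global_rmsd = round(global_rmsd(map, config), 4),
      worse_resolution = if (all(is.na(res))) NA_real_ else max(res, na.rm = TRUE),
      binding_targets = paste(vapply(p$targets, function(t)
        paste0(t$name, " (", t$category, ")"), character(1)), collapse = ";"),
      stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}
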