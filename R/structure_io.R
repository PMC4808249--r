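# PDB reading/writing and the SEQRES <-> coordinate-residue mapping.
#
# The parser covers the record types this pipeline needs (SEQRES, MODRES,
# ATOM, HETATM, MODEL/ENDMDL, REMARK 2/200). Only MODEL 1 is kept: inputs are
# X-ray biological units, not NMR ensembles.

#' Construct an atom record
#'
#' @param name atom label, e.g. `"CA"`.
#' @param element chemical element symbol.
#' @param coords numeric 3-vector, Angstrom.
#' @param altloc alternate location code ("" when absent).
#' @param occupancy occupancy fraction.
#' @keywords internal
new_atom <- function(name, element, coords, altloc = "", occupancy = 1) {
  stopifnot(length(coords) == 3, all(is.finite(coords)), nzchar(element))
  list(name = name, element = element, coords = as.numeric(coords),
       altloc = altloc, occupancy = occupancy)
}

new_residue <- function(name3, chain_id, number, icode = "", atoms = list(),
                        is_het = FALSE) {
  structure(list(name3 = name3, chain_id = chain_id, number = number,
                 icode = icode, atoms = atoms, is_het = is_het),
            class = "pdb_residue")
}

#' Heavy atoms of a residue
#'
#' Returns the atoms of `residue` whose element is neither hydrogen nor
#' deuterium. Idempotent; never returns hydrogens.
#'
#' @param residue a residue object from [read_pdb()].
#' @return list of atom records.
#' @export
heavy_atoms <- function(residue) {
  Filter(function(a) !(toupper(a$element) %in% c("H", "D")), residue$atoms)
}

.atom_element <- function(raw_element, raw_name) {
  el <- trimws(raw_element)
  if (nzchar(el)) return(toupper(el))
  nm <- trimws(raw_name)
  if (grepl("^[0-9]", nm)) return("H")
  # two-character element only when the name starts in column 13 with letters
  first2 <- toupper(gsub("[0-9'\\*]", "", substr(raw_name, 1, 2)))
  if (nchar(trimws(substr(raw_name, 1, 1))) > 0 && nchar(first2) == 2 &&
      first2 %in% c("FE", "MG", "ZN", "MN", "CU", "NA", "CL", "BR", "SE",
                    "CA", "CO", "NI", "CD", "HG", "LI", "RB", "CS", "SR",
                    "BA", "AL", "PT", "AU", "AG", "PB", "XE")) {
    return(first2)
  }
  toupper(substr(gsub("[^A-Za-z]", "", nm), 1, 1))
}

.parse_coord_line <- function(line) {
  list(
    record = trimws(substr(line, 1, 6)),
    name = substr(line, 13, 16),
    altloc = trimws(substr(line, 17, 17)),
    resname = trimws(substr(line, 18, 20)),
    chain = substr(line, 22, 22),
    resnum = suppressWarnings(as.integer(substr(line, 23, 26))),
    icode = trimws(substr(line, 27, 27)),
    x = suppressWarnings(as.numeric(substr(line, 31, 38))),
    y = suppressWarnings(as.numeric(substr(line, 39, 46))),
    z = suppressWarnings(as.numeric(substr(line, 47, 54))),
    occ = suppressWarnings(as.numeric(substr(line, 55, 60))),
    element = if (nchar(line) >= 77) substr(line, 77, 78) else ""
  )
}

#' Read a PDB file
#'
#' Parses a PDB-format text file into a structure-file object: polymer chains
#' with their SEQRES sequences and observed residues, a het-group inventory,
#' a water count and crystallographic metadata. Alternate locations are
#' resolved to the highest-occupancy copy (ties broken by file order); only
#' MODEL 1 of a multi-model file is used.
#'
#' @param path path to a PDB file.
#' @param id optional 4-character id; defaults to HEADER id or the file name.
#' @return an object of class `structure_file` with elements `id`,
#'   `protein_chains` (named list of `protein_structure`), `nucleic_chains`,
#'   `het_residues` (list of het residue objects), `het_groups`
#'   (data.frame `comp_id`, `n_atoms` — one row per het instance), `waters`
#'   (count) and `metadata` (`resolution`, `ph`, `temperature`).
#' @export
read_pdb <- function(path, id = NULL) {
  lines <- readLines(path, warn = FALSE)
  rec <- trimws(substr(lines, 1, 6))

  if (is.null(id)) {
    hdr <- lines[rec == "HEADER"]
    id <- if (length(hdr) && nchar(hdr[1]) >= 66 &&
              nzchar(trimws(substr(hdr[1], 63, 66)))) {
      trimws(substr(hdr[1], 63, 66))
    } else {
      toupper(substr(tools::file_path_sans_ext(basename(path)), 1, 4))
    }
  }

  # --- SEQRES ---------------------------------------------------------------
  seqres3 <- list()
  for (ln in lines[rec == "SEQRES"]) {
    ch <- substr(ln, 12, 12)
    body <- substr(ln, 20, nchar(ln))
    toks <- strsplit(trimws(body), "\\s+")[[1]]
    toks <- toks[nzchar(toks)]
    seqres3[[ch]] <- c(seqres3[[ch]], toks)
  }

  # --- MODRES ---------------------------------------------------------------
  modres <- character(0)
  for (ln in lines[rec == "MODRES"]) {
    het <- trimws(substr(ln, 13, 15))
    std <- trimws(substr(ln, 25, 27))
    if (nzchar(het) && std %in% names(AA_THREE_TO_ONE)) {
      modres[het] <- unname(AA_THREE_TO_ONE[std])
    }
  }

  # --- metadata -------------------------------------------------------------
  resolution <- ph <- temperature <- NA_real_
  for (ln in lines[rec == "REMARK"]) {
    if (grepl("^REMARK   2 RESOLUTION", ln)) {
      fld <- substr(ln, 23, 41)
      v <- regmatches(fld, regexpr("[0-9]+\\.?[0-9]*", fld))
      if (length(v)) resolution <- suppressWarnings(as.numeric(v[1]))
    } else if (grepl("^REMARK 200", ln) && grepl("\\bPH\\b", ln) &&
               grepl(":", ln)) {
      v <- suppressWarnings(as.numeric(trimws(sub(".*:", "", ln))))
      if (!is.na(v)) ph <- v
    } else if (grepl("^REMARK 200", ln) && grepl("TEMPERATURE", ln) &&
               grepl(":", ln)) {
      v <- suppressWarnings(as.numeric(trimws(sub(".*:", "", ln))))
      if (!is.na(v)) temperature <- v
    }
  }
  if (!is.na(resolution) && resolution <= 0) {
    stop("invalid resolution in REMARK 2: ", resolution)
  }

  # --- coordinates (MODEL 1 only) ------------------------------------------
  in_model <- 0L
  keep <- logical(length(lines))
  for (i in seq_along(lines)) {
    r <- rec[i]
    if (r == "MODEL") in_model <- in_model + 1L
    keep[i] <- (r %in% c("ATOM", "HETATM")) && in_model <= 1L
  }
  coord_idx <- which(keep)

  residues <- list()   # keyed by chain|resnum|icode|resname
  res_order <- character(0)
  for (i in coord_idx) {
    p <- .parse_coord_line(lines[i])
    if (is.na(p$resnum) || is.na(p$x) || is.na(p$y) || is.na(p$z)) {
      stop("unparseable coordinate record at line ", i, " of ", path)
    }
    key <- paste(p$chain, p$resnum, p$icode, p$resname, sep = "|")
    if (is.null(residues[[key]])) {
      residues[[key]] <- list(meta = p, from_atom = p$record == "ATOM",
                              atoms = list())
      res_order <- c(res_order, key)
    }
    occ <- if (is.na(p$occ)) 1 else p$occ
    atom <- new_atom(trimws(p$name), .atom_element(p$element, p$name),
                     c(p$x, p$y, p$z), p$altloc, occ)
    anm <- atom$name
    prev <- residues[[key]]$atoms[[anm]]
    if (is.null(prev) || atom$occupancy > prev$occupancy) {
      residues[[key]]$atoms[[anm]] <- atom
    }
  }

  # --- classify residues ----------------------------------------------------
  protein_raw <- list(); nucleic <- list(); het_res <- list(); waters <- 0L
  for (key in res_order) {
    entry <- residues[[key]]
    p <- entry$meta
    res <- new_residue(p$resname, p$chain, p$resnum, p$icode,
                       unname(entry$atoms), is_het = !entry$from_atom)
    if (p$resname %in% WATER_IDS) {
      waters <- waters + 1L
      next
    }
    chain_seqres <- seqres3[[p$chain]]
    polymer_aa <- entry$from_atom && p$resname %in%
      c(names(AA_THREE_TO_ONE), names(MODIFIED_AA_PARENT), names(modres))
    # modified residues are written as HETATM but belong to the polymer
    het_in_polymer <- !entry$from_atom && !is.null(chain_seqres) &&
      p$resname %in% chain_seqres && p$resname %in%
        c(names(MODIFIED_AA_PARENT), names(modres))
    if (polymer_aa || het_in_polymer) {
      res$is_het <- FALSE
      protein_raw[[p$chain]] <- c(protein_raw[[p$chain]], list(res))
    } else if (entry$from_atom && p$resname %in% NUCLEOTIDE_IDS) {
      nucleic[[p$chain]] <- c(nucleic[[p$chain]], list(res))
    } else {
      het_res <- c(het_res, list(res))
    }
  }

  # --- build protein chains -------------------------------------------------
  protein_chains <- list()
  aa_like <- vapply(seqres3, function(s3)
    mean(s3 %in% c(names(AA_THREE_TO_ONE), names(MODIFIED_AA_PARENT),
                   names(modres))) > 0.5, logical(1))
  for (ch in union(names(protein_raw), names(seqres3)[aa_like])) {
    s3 <- seqres3[[ch]]
    obs <- protein_raw[[ch]]
    if (is.null(s3)) {
      if (!is.null(obs)) {
        stop("missing SEQRES for chain '", ch, "' in ", path)
      }
      next
    }
    protein_chains[[ch]] <- map_observed_to_seqres(
      list(chain_id = ch, seqres3 = s3, observed = obs, modres = modres),
      file_id = id)
  }

  nucleic_chains <- lapply(names(nucleic), function(ch) {
    list(chain_id = ch, residues = nucleic[[ch]],
         seqres3 = seqres3[[ch]])
  })
  names(nucleic_chains) <- names(nucleic)

  het_groups <- if (length(het_res)) {
    data.frame(
      comp_id = vapply(het_res, function(r) r$name3, character(1)),
      n_atoms = vapply(het_res, function(r) length(r$atoms), integer(1)),
      stringsAsFactors = FALSE)
  } else {
    data.frame(comp_id = character(0), n_atoms = integer(0))
  }

  structure(list(id = id, protein_chains = protein_chains,
                 nucleic_chains = nucleic_chains, het_residues = het_res,
                 het_groups = het_groups, waters = waters,
                 metadata = list(resolution = resolution, ph = ph,
                                 temperature = temperature)),
            class = "structure_file")
}

#' Map observed residues onto the SEQRES sequence
#'
#' Assigns each coordinate-bearing residue of a chain to a 1-based SEQRES
#' index. A uniform author-numbering offset is tried first (smallest absolute
#' offset wins); if insertion codes or irregular numbering defeat that, a
#' leftmost gapless subsequence embedding is used. SEQRES indices without an
#' assigned residue form the disordered set.
#'
#' @param chain list with `chain_id`, `seqres3` (3-letter codes in SEQRES
#'   order), `observed` (residue objects in file order) and optionally
#'   `modres` (named translation for modified residues).
#' @param file_id id carried into the result.
#' @return an object of class `protein_structure`: `file_id`, `chain_id`,
#'   `seqres` (1-letter string), `seqres3`, `observed` (list mapping SEQRES
#'   index to residue, `NULL` where disordered), `observed_idx` (integer
#'   vector of assigned indices).
#' @export
map_observed_to_seqres <- function(chain, file_id = "XXXX") {
  s3 <- chain$seqres3
  modres <- chain$modres %||% character(0)
  letter_of <- function(n3) {
    n3 <- toupper(trimws(n3))
    if (n3 %in% names(modres)) unname(modres[n3]) else .aa_from_three(n3)
  }
  s_letters <- vapply(s3, letter_of, character(1))
  L <- length(s_letters)
  seqres <- paste(s_letters, collapse = "")
  obs <- chain$observed %||% list()

  observed <- vector("list", L)
  idx <- integer(0)

  if (length(obs)) {
    o_letters <- vapply(obs, function(r) letter_of(r$name3), character(1))
    numbers <- vapply(obs, function(r) r$number, numeric(1))
    icodes <- vapply(obs, function(r) r$icode, character(1))

    assignment <- NULL
    if (!any(nzchar(icodes)) && !anyDuplicated(numbers)) {
      # offset scan: seqres index = author number + delta
      deltas <- sort(unique(seq_len(L) - rep(numbers, each = L)))
      deltas <- deltas[order(abs(deltas), deltas)]
      for (d in deltas) {
        pos <- numbers + d
        if (any(pos < 1 | pos > L)) next
        ok <- s_letters[pos] == o_letters | s_letters[pos] == "X" |
          o_letters == "X"
        if (all(ok)) { assignment <- pos; break }
      }
    }
    if (is.null(assignment)) {
      # leftmost gapless subsequence embedding
      assignment <- integer(length(obs))
      j <- 1L
      for (k in seq_along(obs)) {
        while (j <= L && !(s_letters[j] == o_letters[k] ||
                           s_letters[j] == "X" || o_letters[k] == "X")) {
          j <- j + 1L
        }
        if (j > L) {
          stop("observed residues of chain '", chain$chain_id,
               "' cannot be embedded in SEQRES without mismatches")
        }
        assignment[k] <- j
        j <- j + 1L
      }
    }
    for (k in seq_along(obs)) observed[[assignment[k]]] <- obs[[k]]
    idx <- sort(assignment)
  }

  structure(list(file_id = file_id, chain_id = chain$chain_id,
                 seqres = seqres, seqres3 = s3, observed = observed,
                 observed_idx = idx),
            class = "protein_structure")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' SEQRES indices without coordinates
#' @param ps a `protein_structure`.
#' @return integer vector of disordered SEQRES indices.
#' @export
disordered_indices <- function(ps) {
  setdiff(seq_len(nchar(ps$seqres)), ps$observed_idx)
}

#' C-alpha coordinates on the SEQRES ruler
#'
#' @param ps a `protein_structure`.
#' @return L x 3 matrix, `NA` rows where no CA is observed.
#' @export
ca_matrix <- function(ps) {
  L <- nchar(ps$seqres)
  m <- matrix(NA_real_, L, 3)
  for (i in ps$observed_idx) {
    r <- ps$observed[[i]]
    for (a in r$atoms) {
      if (a$name == "CA") { m[i, ] <- a$coords; break }
    }
  }
  m
}

.fmt_atom_line <- function(record, serial, name, resname, chain, resnum,
                           xyz, occ = 1, bfac = 0, element = "") {
  name_field <- if (nchar(name) >= 4) substr(name, 1, 4)
    else if (nchar(element) == 2) sprintf("%-4s", name)
    else sprintf(" %-3s", name)
  sprintf("%-6s%5d %4s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          record, serial %% 100000, name_field, resname, chain, resnum %% 10000,
          xyz[1], xyz[2], xyz[3], occ, bfac, element)
}

.residue_lines <- function(res, serial, record = NULL) {
  record <- record %||% if (isTRUE(res$is_het)) "HETATM" else "ATOM"
  out <- character(length(res$atoms))
  for (k in seq_along(res$atoms)) {
    a <- res$atoms[[k]]
    out[k] <- .fmt_atom_line(record, serial, a$name, res$name3, res$chain_id,
                             res$number, a$coords, a$occupancy,
                             element = a$element)
    serial <- serial + 1L
  }
  list(lines = out, serial = serial)
}

.seqres_lines <- function(chain_id, s3) {
  n <- length(s3)
  out <- character(0)
  row <- 1L
  for (start in seq(1, n, by = 13)) {
    toks <- s3[start:min(n, start + 12)]
    out <- c(out, sprintf("SEQRES %3d %1s %4d  %s", row, chain_id, n,
                          paste(sprintf("%-3s", toks), collapse = " ")))
    row <- row + 1L
  }
  out
}

#' Write structures to a PDB file
#'
#' Writes one or two models in PDB v3.3 fixed-width format. With two models,
#' MODEL 1 is the before state and MODEL 2 the after state (callers transform
#' the after coordinates into the before frame beforehand). Each model may be
#' a `protein_structure` or a full `structure_file` (polymer + het groups).
#'
#' @param models a single structure or a list of one/two structures.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(models, path) {
  if (inherits(models, "protein_structure") ||
      inherits(models, "structure_file")) {
    models <- list(models)
  }
  stopifnot(length(models) %in% c(1L, 2L))
  out <- character(0)

  seqres_of <- function(m) {
    if (inherits(m, "protein_structure")) {
      .seqres_lines(m$chain_id, m$seqres3)
    } else {
      unlist(lapply(m$protein_chains, function(pc)
        .seqres_lines(pc$chain_id, pc$seqres3)), use.names = FALSE)
    }
  }
  out <- c(out, seqres_of(models[[1]]))

  for (mi in seq_along(models)) {
    m <- models[[mi]]
    out <- c(out, sprintf("MODEL     %4d", mi))
    serial <- 1L
    emit_chain <- function(pc) {
      for (i in pc$observed_idx) {
        rl <- .residue_lines(pc$observed[[i]], serial, record = "ATOM")
        out <<- c(out, rl$lines)
        serial <<- rl$serial
      }
      out <<- c(out, sprintf("TER   %5d      %-3s %1s", serial,
                             pc$observed[[max(pc$observed_idx)]]$name3 %||% "",
                             pc$chain_id))
      serial <<- serial + 1L
    }
    if (inherits(m, "protein_structure")) {
      emit_chain(m)
    } else {
      for (pc in m$protein_chains) emit_chain(pc)
      for (hr in m$het_residues) {
        rl <- .residue_lines(hr, serial, record = "HETATM")
        out <- c(out, rl$lines)
        serial <- rl$serial
      }
    }
    out <- c(out, "ENDMDL")
  }
  out <- c(out, "END")
  writeLines(out, path)
  invisible(path)
}

#' Apply a rigid transform to a structure's coordinates
#'
#' @param ps a `protein_structure`.
#' @param rotation 3x3 rotation matrix.
#' @param translation length-3 vector.
#' @return the transformed `protein_structure`.
#' @export
transform_structure <- function(ps, rotation, translation) {
  for (i in ps$observed_idx) {
    r <- ps$observed[[i]]
    for (k in seq_along(r$atoms)) {
      r$atoms[[k]]$coords <-
        as.numeric(rotation %*% r$atoms[[k]]$coords + translation)
    }
    ps$observed[[i]] <- r
  }
  ps
}
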