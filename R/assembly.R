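# Assembling every per-position track into one profile set on the reference
# ruler, user annotation-track ingestion, TSV/JSON serialisation and the
# command-line entry point.

#' 11-character structure-pair id
#'
#' Characters 1-5 are the before PDB id + chain, 6 the separator `_`, 7-11
#' the after PDB id + chain. Chain case is preserved verbatim.
#'
#' @param before_id,after_id 4-character PDB ids.
#' @param before_chain,after_chain 1-character chain ids.
#' @return the 11-character id, e.g. `"1G7RA_1G7TA"`.
#' @export
structure_pair_id <- function(before_id, before_chain, after_id, after_chain) {
  ok <- function(id, ch) nchar(id) == 4 && nchar(ch) == 1
  if (!ok(before_id, before_chain) || !ok(after_id, after_chain)) {
    stop("pair ids must be 4-character file ids with 1-character chains")
  }
  paste0(before_id, before_chain, "_", after_id, after_chain)
}

#' Read an annotation interval track TSV
#'
#' Format: tab-separated `track`, `label`, `start`, `end` (closed 1-based
#' intervals on reference positions). Intervals are clipped to `[1, L]`.
#'
#' @param path TSV path.
#' @param L reference length for clipping.
#' @return data.frame of intervals.
#' @export
read_annotations <- function(path, L) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("track", "label", "start", "end")
  if (!all(need %in% names(df))) {
    stop("annotation TSV needs columns: ", paste(need, collapse = ", "))
  }
  df$start <- pmax(1L, as.integer(df$start))
  df$end <- pmin(as.integer(L), as.integer(df$end))
  df <- df[df$start <= df$end, , drop = FALSE]
  df
}

.interval_membership <- function(ann, track, L) {
  v <- rep("", L)
  rows <- ann[ann$track == track, , drop = FALSE]
  for (k in seq_len(nrow(rows))) {
    rng <- rows$start[k]:rows$end[k]
    v[rng] <- ifelse(v[rng] == "", rows$label[k],
                     paste(v[rng], rows$label[k], sep = ";"))
  }
  v
}

#' Assemble the full profile set for a structure pair
#'
#' Runs every computable stage — residue map, CCP, global RMSD, binding-site
#' and name tracks, before/after secondary structure, hydropathy, optional
#' conservation and annotation tracks — and returns them keyed to the
#' reference. Tracks whose inputs are absent are absent, never fabricated.
#'
#' @param before,after `protein_structure` objects (free / bound states).
#' @param ref a `reference_sequence`.
#' @param targets binding targets of the pair (see
#'   [extract_binding_targets()]); may be an empty list.
#' @param msa optional `msa` object for the conservation track.
#' @param annotations optional annotation data.frame ([read_annotations()]).
#' @param config a [ccp_config()].
#' @param site_cutoff,name_cutoff binding-profile cutoffs in Angstrom.
#' @param before_meta,after_meta metadata lists (resolution, pH, temperature).
#' @return object of class `profile_set`.
#' @export
assemble <- function(before, after, ref, targets = list(), msa = NULL,
                     annotations = NULL, config = ccp_config(),
                     site_cutoff = 5.0, name_cutoff = 3.0,
                     before_meta = list(), after_meta = list()) {
  map <- build_residue_map(after, before, ref)
  L <- ref$length

  tracks <- list(
    ccp = compute_ccp(map, config),
    binding_flag = binding_site_profile(map, targets, site_cutoff),
    binding_names = associate_names(map, targets, name_cutoff),
    ss_after = overlay_disorder(map, state = 1),
    ss_before = overlay_disorder(map, state = 2),
    hydropathy = hydropathy_profile(ref)
  )
  if (!is.null(msa)) tracks$conservation <- conservation_profile(msa)

  interval_tracks <- list()
  if (!is.null(annotations)) {
    for (tr in unique(annotations$track)) {
      interval_tracks[[tr]] <- .interval_membership(annotations, tr, L)
    }
  }

  res <- c(before_meta$resolution, after_meta$resolution)
  res <- res[!is.na(res)]
  metadata <- list(
    pair_id = structure_pair_id(before$file_id, before$chain_id,
                                after$file_id, after$chain_id),
    global_rmsd = global_rmsd(map, config),
    worse_resolution = if (length(res)) max(res) else NA_real_,
    ph = c(before = before_meta$ph %||% NA_real_,
           after = after_meta$ph %||% NA_real_),
    temperature = c(before = before_meta$temperature %||% NA_real_,
                    after = after_meta$temperature %||% NA_real_),
    loop_fraction = c(before = loop_fraction(tracks$ss_before),
                      after = loop_fraction(tracks$ss_after)),
    binding_targets = vapply(targets, function(t)
      paste0(t$name, " (", t$category, ")"), character(1))
  )

  structure(list(ref = ref, map = map, tracks = tracks,
                 interval_tracks = interval_tracks, metadata = metadata),
            class = "profile_set")
}

.fmt_num <- function(x, digits) {
  ifelse(is.na(x), "NA", formatC(x, format = "f", digits = digits))
}

#' Serialise a profile set to wide TSV
#'
#' One row per reference position with fixed float formatting (4 decimals
#' for Angstrom tracks, 3 for conservation and hydropathy); nulls are "NA".
#' Deterministic: identical inputs give byte-identical output.
#'
#' @param ps a `profile_set`.
#' @param path output path.
#' @return the data.frame, invisibly.
#' @export
write_tsv <- function(ps, path) {
  L <- ps$ref$length
  tk <- ps$tracks
  df <- data.frame(
    position = seq_len(L),
    ref_aa = strsplit(ps$ref$sequence, "")[[1]],
    ccp = .fmt_num(tk$ccp$values, 4),
    binding_flag = ifelse(is.na(tk$binding_flag$values), "NA",
                          ifelse(tk$binding_flag$values, "true", "false")),
    binding_names = ifelse(is.na(tk$binding_names$values), "NA",
                           tk$binding_names$values),
    ss_before = tk$ss_before$values,
    ss_after = tk$ss_after$values,
    conservation = if (!is.null(tk$conservation)) {
      .fmt_num(tk$conservation$values, 3)
    } else "NA",
    hydropathy = .fmt_num(tk$hydropathy$values, 3),
    stringsAsFactors = FALSE)
  for (tr in names(ps$interval_tracks)) {
    df[[tr]] <- ps$interval_tracks[[tr]]
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}

#' Serialise a profile set to JSON
#'
#' Mirrors the TSV with native nulls for missing values and the pair
#' metadata block included.
#'
#' @inheritParams write_tsv
#' @return `path`, invisibly.
#' @export
write_json <- function(ps, path) {
  tk <- ps$tracks
  payload <- list(
    reference = list(id = ps$ref$id, length = ps$ref$length,
                     sequence = ps$ref$sequence),
    metadata = ps$metadata,
    tracks = c(
      lapply(tk, function(t) t$values),
      ps$interval_tracks
    )
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       na = "null", null = "null", pretty = TRUE)
  invisible(path)
}

#' Read back a JSON profile set
#' @param path JSON written by [write_json()].
#' @return list mirroring the payload.
#' @export
read_profile_json <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}

#' Run the full profile pipeline on a pair of PDB files
#'
#' Convenience wrapper used by the CLI: reads both files, extracts binding
#' targets, assembles the profile set and writes `<prefix>.tsv`,
#' `<prefix>.json`, `<prefix>.superposed.pdb` (MODEL 1 before, MODEL 2 after
#' transformed into the before frame) and `<prefix>.meta.txt`.
#'
#' @param before_path,after_path PDB files (free / bound states).
#' @param before_chain,after_chain chain ids.
#' @param ref_path reference FASTA.
#' @param out_prefix output path prefix.
#' @param msa_path optional aligned FASTA.
#' @param annotations_path optional annotation TSV.
#' @param config a [ccp_config()].
#' @param site_cutoff,name_cutoff binding cutoffs in Angstrom.
#' @return the `profile_set`, invisibly.
#' @export
profile_pair <- function(before_path, after_path, before_chain, after_chain,
                         ref_path, out_prefix, msa_path = NULL,
                         annotations_path = NULL, config = ccp_config(),
                         site_cutoff = 5.0, name_cutoff = 3.0) {
  Fb <- read_pdb(before_path)
  Fa <- read_pdb(after_path)
  ref <- read_reference(ref_path)
  if (is.null(Fb$protein_chains[[before_chain]])) {
    stop("chain '", before_chain, "' not in ", before_path)
  }
  if (is.null(Fa$protein_chains[[after_chain]])) {
    stop("chain '", after_chain, "' not in ", after_path)
  }
  before <- Fb$protein_chains[[before_chain]]
  after <- Fa$protein_chains[[after_chain]]
  targets <- extract_binding_targets(Fa, Fb, after_chain, before_chain,
                                     cutoff = site_cutoff)
  msa <- if (!is.null(msa_path)) read_msa(msa_path, ref)
  ann <- if (!is.null(annotations_path)) {
    read_annotations(annotations_path, ref$length)
  }
  ps <- assemble(before, after, ref, targets = targets, msa = msa,
                 annotations = ann, config = config,
                 site_cutoff = site_cutoff, name_cutoff = name_cutoff,
                 before_meta = Fb$metadata, after_meta = Fa$metadata)

  write_tsv(ps, paste0(out_prefix, ".tsv"))
  write_json(ps, paste0(out_prefix, ".json"))

  fit <- global_superposition(ps$map, config)
  after_in_before_frame <- transform_structure(after, fit$rotation,
                                               fit$translation)
  write_pdb(list(before, after_in_before_frame),
            paste0(out_prefix, ".superposed.pdb"))

  meta <- ps$metadata
  writeLines(c(
    paste0("pair_id\t", meta$pair_id),
    paste0("global_rmsd\t", .fmt_num(meta$global_rmsd, 4)),
    paste0("worse_resolution\t", .fmt_num(meta$worse_resolution, 2)),
    paste0("loop_fraction_before\t", .fmt_num(meta$loop_fraction[["before"]], 2)),
    paste0("loop_fraction_after\t", .fmt_num(meta$loop_fraction[["after"]], 2)),
    paste0("binding_targets\t", paste(meta$binding_targets, collapse = ";"))
  ), paste0(out_prefix, ".meta.txt"))

  invisible(ps)
}

#' Command-line entry point
#'
#' Two subcommands:
#' \describe{
#'   \item{pair}{`--pdb-dir D --ref ref.fasta --out pairs.tsv` — enumerate
#'     valid before/after pairs among the PDB files of a directory.}
#'   \item{profile}{`--before F.pdb --before-chain A --after G.pdb
#'     --after-chain A --ref ref.fasta [--msa msa.fasta]
#'     [--annotations ann.tsv] [--window 21] [--site-cutoff 5.0]
#'     [--name-cutoff 3.0] [--estimator reweighted|least_squares]
#'     --out prefix` — run the full profile pipeline on one pair.}
#' }
#'
#' @param args character vector (defaults to `commandArgs(TRUE)`).
#' @return exit status, invisibly.
#' @export
ccprofiler_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- function() {
    message("usage: ccprofiler pair --pdb-dir D --ref ref.fasta --out pairs.tsv")
    message("       ccprofiler profile --before F.pdb --before-chain A ",
            "--after G.pdb --after-chain A --ref ref.fasta --out prefix ",
            "[--msa msa.fasta] [--annotations ann.tsv] [--window 21] ",
            "[--site-cutoff 5.0] [--name-cutoff 3.0] ",
            "[--estimator reweighted|least_squares]")
    invisible(1L)
  }
  if (!length(args)) return(usage())
  cmd <- args[1]
  opts <- list()
  i <- 2
  while (i <= length(args)) {
    key <- sub("^--", "", args[i])
    opts[[key]] <- args[i + 1]
    i <- i + 2
  }
  t0 <- Sys.time()
  log_stage <- function(stage) {
    message(sprintf("[%s] %s (%.2fs elapsed)", format(Sys.time(), "%H:%M:%S"),
                    stage, as.numeric(difftime(Sys.time(), t0, units = "secs"))))
  }

  if (cmd == "pair") {
    if (is.null(opts$`pdb-dir`) || is.null(opts$ref) || is.null(opts$out)) {
      return(usage())
    }
    log_stage("reading PDB files")
    paths <- list.files(opts$`pdb-dir`, pattern = "\\.(pdb|ent)$",
                        full.names = TRUE)
    files <- lapply(paths, read_pdb)
    ref <- read_reference(opts$ref)
    log_stage("enumerating pairs")
    pairs <- find_pairs(files, ref)
    write_pair_report(pairs, ref, opts$out)
    log_stage(paste(length(pairs), "pair(s) written"))
    return(invisible(0L))
  }
  if (cmd == "profile") {
    need <- c("before", "before-chain", "after", "after-chain", "ref", "out")
    if (!all(need %in% names(opts))) return(usage())
    window <- as.integer(opts$window %||% "21")
    if (window %% 2 == 0) stop("--window must be odd")
    config <- ccp_config(half_window = (window - 1L) %/% 2L,
                         estimator = opts$estimator %||% "reweighted")
    log_stage("profiling pair")
    profile_pair(opts$before, opts$after, opts$`before-chain`,
                 opts$`after-chain`, opts$ref, opts$out,
                 msa_path = opts$msa, annotations_path = opts$annotations,
                 config = config,
                 site_cutoff = as.numeric(opts$`site-cutoff` %||% "5.0"),
                 name_cutoff = as.numeric(opts$`name-cutoff` %||% "3.0"))
    log_stage("done")
    return(invisible(0L))
  }
  usage()
}
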