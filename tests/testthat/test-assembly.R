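assembled_fixture <- function(with_msa = TRUE, with_ann = TRUE, seed = 81) {
  pair <- make_hinge_pair(length = 50, hinge = 25, angle = 25, seed = seed,
                          delete_free = 10:11)
  ref <- reference_sequence("ref", pair$free$protein_chains[["A"]]$seqres)
  targets <- extract_binding_targets(pair$bound, pair$free, "A", "A")
  msa <- if (with_msa) {
    m <- make_msa(L = 50, n = 6, conserved_positions = c(5, 20), seed = seed)
    m$ref <- ref; m$ids[1] <- ref$id
    msa_from_matrix(m$rows, m$ids, reference_sequence(ref$id,
      paste(m$rows[1, ], collapse = "")))
  }
  ann <- if (with_ann) {
    path <- tempfile(fileext = ".tsv")
    writeLines(c("track\tlabel\tstart\tend",
                 "domain\tGdomain\t1\t30",
                 "phosphosite\tpS\t12\t12",
                 "domain\tCterm\t28\t60"), path)
    read_annotations(path, ref$length)
  }
  ps <- assemble(pair$free$protein_chains[["A"]],
                 pair$bound$protein_chains[["A"]],
                 ref, targets = targets, msa = msa, annotations = ann,
                 before_meta = pair$free$metadata,
                 after_meta = pair$bound$metadata)
  list(ps = ps, ref = ref, msa = msa)
}

test_that("assemble produces equal-length tracks; absent inputs stay absent", {
  fx <- assembled_fixture(with_msa = FALSE, with_ann = FALSE)
  ps <- fx$ps
  expect_null(ps$tracks$conservation)
  lens <- vapply(ps$tracks, function(t) t$length, numeric(1))
  expect_true(all(lens == fx$ref$length))
  expect_length(ps$interval_tracks, 0)
})

test_that("metadata carries pair id, worse resolution and loop fractions", {
  fx <- assembled_fixture()
  md <- fx$ps$metadata
  expect_equal(md$pair_id, "SYNFA_SYNBA")
  expect_equal(md$worse_resolution, 1.8)
  expect_true(md$global_rmsd > 0)
  expect_true(all(is.finite(md$loop_fraction)))
  expect_match(md$binding_targets, "GNP")
})

test_that("interval annotations are clipped and rendered as membership", {
  fx <- assembled_fixture()
  it <- fx$ps$interval_tracks
  expect_setequal(names(it), c("domain", "phosphosite"))
  expect_equal(it$domain[1], "Gdomain")
  expect_equal(it$domain[29], "Gdomain;Cterm")   # overlap joins labels
  expect_equal(it$domain[50], "Cterm")           # clipped at L = 50
  expect_equal(it$phosphosite[12], "pS")
  expect_equal(it$phosphosite[13], "")
})

test_that("TSV serialisation: header + L rows, NA nulls, deterministic", {
  fx <- assembled_fixture()
  p1 <- tempfile(fileext = ".tsv"); p2 <- tempfile(fileext = ".tsv")
  write_tsv(fx$ps, p1)
  write_tsv(fx$ps, p2)
  l1 <- readLines(p1)
  expect_length(l1, fx$ref$length + 1)
  expect_identical(l1, readLines(p2))            # byte-identical
  df <- read.delim(p1, stringsAsFactors = FALSE, colClasses = "character",
                   na.strings = NULL)
  # free copy lacks coords at 10..11 -> CCP null serialised as NA
  expect_equal(df$ccp[10], "NA")
  expect_equal(df$ss_before[10], "D")
})

test_that("JSON round-trip reproduces every track including nulls", {
  fx <- assembled_fixture()
  path <- tempfile(fileext = ".json")
  write_json(fx$ps, path)
  back <- read_profile_json(path)
  expect_equal(back$reference$length, fx$ref$length)
  ccp <- fx$ps$tracks$ccp$values
  expect_equal(is.na(back$tracks$ccp), is.na(ccp))
  expect_equal(back$tracks$ccp[!is.na(ccp)], ccp[!is.na(ccp)],
               tolerance = 1e-12)
  expect_equal(back$tracks$ss_before, fx$ps$tracks$ss_before$values)
  expect_equal(back$tracks$binding_flag[!is.na(back$tracks$binding_flag)],
               fx$ps$tracks$binding_flag$values[
                 !is.na(fx$ps$tracks$binding_flag$values)])
})

test_that("structure_pair_id formats and validates", {
  expect_equal(structure_pair_id("1G7R", "A", "1G7T", "A"), "1G7RA_1G7TA")
  expect_equal(structure_pair_id("1ABC", "a", "2DEF", "b"), "1ABCa_2DEFb")
  expect_error(structure_pair_id("1ABCD", "A", "2DEF", "B"), "4-character")
})

test_that("profile_pair end-to-end writes all four outputs", {
  pair <- make_hinge_pair(length = 40, hinge = 20, angle = 20, seed = 82)
  dir <- tempfile(); dir.create(dir)
  before_p <- file.path(dir, "free.pdb"); after_p <- file.path(dir, "bound.pdb")
  write_pdb(pair$free, before_p); write_pdb(pair$bound, after_p)
  ref_p <- file.path(dir, "ref.fasta")
  writeLines(c(">refseq", pair$free$protein_chains[["A"]]$seqres), ref_p)
  prefix <- file.path(dir, "out")
  ps <- profile_pair(before_p, after_p, "A", "A", ref_p, prefix)
  expect_true(all(file.exists(paste0(prefix,
    c(".tsv", ".json", ".superposed.pdb", ".meta.txt")))))
  sup <- readLines(paste0(prefix, ".superposed.pdb"))
  expect_equal(sum(grepl("^MODEL", sup)), 2)
  meta <- readLines(paste0(prefix, ".meta.txt"))
  expect_match(meta[1], "pair_id\t")
})

test_that("the CLI profile subcommand runs and logs stages", {
  pair <- make_hinge_pair(length = 30, hinge = 15, angle = 15, seed = 83)
  dir <- tempfile(); dir.create(dir)
  before_p <- file.path(dir, "free.pdb"); after_p <- file.path(dir, "bound.pdb")
  write_pdb(pair$free, before_p); write_pdb(pair$bound, after_p)
  ref_p <- file.path(dir, "ref.fasta")
  writeLines(c(">refseq", pair$free$protein_chains[["A"]]$seqres), ref_p)
  msgs <- capture.output(
    status <- ccprofiler_main(c("profile", "--before", before_p,
                                "--before-chain", "A", "--after", after_p,
                                "--after-chain", "A", "--ref", ref_p,
                                "--out", file.path(dir, "cli"),
                                "--estimator", "least_squares")),
    type = "message")
  expect_equal(status, 0L)
  expect_true(any(grepl("profiling pair", msgs)))
  expect_true(file.exists(file.path(dir, "cli.tsv")))
})
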