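test_that("map_fragment places exact substrings with 100% identity", {
  ref <- reference_sequence("ref", "MKTAYIAKQRQISFVKSHFSRQLEERLGLIEVQ")  # 33 aa
  frag <- substr(ref$sequence, 5, 20)
  m <- map_fragment(frag, ref)
  expect_equal(m$offset, 5)
  expect_equal(m$identity, 100)
  expect_true(m$valid)
  expect_lt(m$evalue, 1e-3)
})

test_that("identity boundary: 15/16 = 93.75% fails, 19/20 = 95% passes", {
  ref <- reference_sequence("ref", "MKTAYIAKQRQISFVKSHFSRQLEERLGLIEVQ")
  frag16 <- substr(ref$sequence, 3, 18)
  substr(frag16, 8, 8) <- if (substr(frag16, 8, 8) == "W") "Y" else "W"
  m <- map_fragment(frag16, ref)
  expect_equal(m$identity, 100 * 15 / 16)
  expect_false(m$valid)
  expect_true("identity" %in% m$reasons)

  frag20 <- substr(ref$sequence, 1, 20)
  substr(frag20, 10, 10) <- if (substr(frag20, 10, 10) == "W") "Y" else "W"
  m <- map_fragment(frag20, ref)
  expect_equal(m$identity, 95)
  expect_true(m$valid)
})

test_that("a fragment needing a gap reports an indel", {
  ref <- reference_sequence("ref",
    "MKTAYIAKQRQISFVKSHFSRQLEERLGLIEVQAPILSRVGDGTQDNLSGAEKAVQ")
  # delete 3 interior residues -> fragment requires a deletion gap
  frag <- paste0(substr(ref$sequence, 1, 20), substr(ref$sequence, 24, 45))
  m <- map_fragment(frag, ref)
  expect_false(m$valid)
  expect_true("indel" %in% m$reasons)
})

test_that("fragment longer than reference is not embeddable", {
  ref <- reference_sequence("ref", "MKTAYIAK")
  m <- map_fragment("MKTAYIAKQRQISF", ref)
  expect_false(m$valid)
  expect_equal(m$reasons, "not embeddable")
})

test_that("map_fragment agrees with the exhaustive offset-scan oracle", {
  set.seed(21)
  aas <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  for (rep in 1:25) {
    L <- sample(30:200, 1)
    refseq <- paste(sample(aas, L, replace = TRUE), collapse = "")
    ref <- reference_sequence("ref", refseq)
    m_len <- sample(5:min(50, L), 1)
    start <- sample(L - m_len + 1, 1)
    frag <- substr(refseq, start, start + m_len - 1)
    # sprinkle up to 2 mismatches
    for (k in seq_len(sample(0:2, 1))) {
      p <- sample(m_len, 1)
      substr(frag, p, p) <- sample(aas, 1)
    }
    oracle <- offset_scan_oracle(frag, refseq)
    m <- map_fragment(frag, ref)
    expect_equal(m$offset, oracle$offset)
    expect_equal(m$identity, 100 * oracle$matches / m_len)
  }
})

test_that("evalue is Karlin-Altschul closed form and monotone in score", {
  # perfect 100-aa match scores far below threshold
  set.seed(22)
  aas <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  seq100 <- paste(sample(aas, 100, replace = TRUE), collapse = "")
  ref <- reference_sequence("ref", paste0(seq100,
    paste(sample(aas, 50, replace = TRUE), collapse = "")))
  m <- map_fragment(seq100, ref)
  expect_lt(m$evalue, 1e-50)

  # typical 5-mer against a 10000-aa reference fails the threshold
  ref_big <- reference_sequence("big",
    paste(sample(aas, 10000, replace = TRUE), collapse = ""))
  m5 <- map_fragment("AKQRL", ref_big)
  expect_gte(m5$evalue, 1e-3)
  expect_false(m5$valid)

  # strictly decreasing in score at fixed lengths
  evs <- vapply(seq(10, 100, by = 10), function(s) evalue(s, 50, 500),
                numeric(1))
  expect_true(all(diff(evs) < 0))
})

test_that("build_residue_map classifies observed/disordered/null", {
  set.seed(31)
  aas <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  refseq <- paste(sample(aas, 40, replace = TRUE), collapse = "")
  ref <- reference_sequence("ref", refseq)
  # s1 covers 1..30 (coords missing at 12..14), s2 covers 11..40
  mk <- function(first, last, missing = integer(0), id) {
    n <- last - first + 1
    lets <- strsplit(substr(refseq, first, last), "")[[1]]
    res <- lapply(setdiff(seq_len(n), missing), function(i)
      new_residue(unname(ccprofiler:::AA_ONE_TO_THREE[lets[i]]), "A", i,
                  atoms = list(
        new_atom("CA", "C", c((first + i) * 3.8, 0, 0)))))
    map_observed_to_seqres(list(chain_id = "A",
      seqres3 = unname(ccprofiler:::AA_ONE_TO_THREE[lets]),
      observed = res), file_id = id)
  }
  s1 <- mk(1, 30, missing = 12:14, id = "AAAA")
  s2 <- mk(11, 40, id = "BBBB")
  map <- build_residue_map(s1, s2, ref)

  expect_equal(map$overlap, c(11, 30))
  expect_equal(unique(map$status1[31:40]), "null")
  expect_equal(unique(map$status2[1:10]), "null")
  expect_equal(map$status1[12:14], rep("disordered", 3))
  expect_equal(unique(map$status1[15:30]), "observed")

  # the three classes partition [1, L] per structure
  for (st in list(map$status1, map$status2)) {
    expect_length(st, 40)
    expect_true(all(st %in% c("observed", "disordered", "null")))
  }

  # symmetric under swapping
  map_swap <- build_residue_map(s2, s1, ref)
  expect_equal(map_swap$status1, map$status2)
  expect_equal(map_swap$status2, map$status1)
})

test_that("non-overlapping placements raise a no-overlap error", {
  set.seed(32)
  aas <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  ref <- reference_sequence("ref",
    paste(sample(aas, 40, replace = TRUE), collapse = ""))
  mk <- function(first, n, id) {
    lets <- strsplit(substr(ref$sequence, first, first + n - 1), "")[[1]]
    res <- lapply(seq_len(n), function(i)
      new_residue(unname(ccprofiler:::AA_ONE_TO_THREE[lets[i]]), "A", i,
                  atoms = list(new_atom("CA", "C", c(i * 3.8, 0, 0)))))
    map_observed_to_seqres(list(chain_id = "A",
      seqres3 = unname(ccprofiler:::AA_ONE_TO_THREE[lets]),
      observed = res), file_id = id)
  }
  s1 <- mk(1, 12, "AAAA"); s2 <- mk(25, 12, "BBBB")
  expect_error(build_residue_map(s1, s2, ref), "no overlap")
})
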