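test_that("candidate generation honours the primer heuristics and seed", {
  cands <- generate_address_candidates(200, seed = 4)
  expect_length(cands, 200L)
  expect_true(all(nchar(cands) == 20L))
  gc <- gc_fraction(cands)
  expect_true(all(gc >= 0.40 & gc <= 0.60))
  expect_true(all(max_homopolymer(cands) <= 3L))
  expect_identical(cands, generate_address_candidates(200, seed = 4))
  expect_false(identical(cands, generate_address_candidates(200, seed = 5)))
})

test_that("greedy mutual orthogonality equals the brute-force oracle", {
  expect_identical(as.character(mutual_orthogonality_filter("ACGTACGTACGTACGTACGT")),
                   "ACGTACGTACGTACGTACGT")
  dup <- c("ACGTACGTACGTACGTACGT", "ACGTACGTACGTACGTACGT")
  expect_identical(as.character(mutual_orthogonality_filter(dup)), dup[1])
  withr::with_seed(13, {
    cands <- random_dna(100, 20)
  })
  got <- as.character(mutual_orthogonality_filter(cands, 6))
  expect_identical(got, oracle_greedy_filter(cands, 6))
  # a tighter threshold never admits more addresses
  expect_lte(length(as.character(mutual_orthogonality_filter(cands, 10))),
             length(got))
})

test_that("payload conflicts agree with the exhaustive window-scan oracle", {
  withr::with_seed(17, {
    addr <- random_dna(1, 20)
    strand <- paste0(random_dna(1, 40), addr, random_dna(1, 40))
  })
  expect_true(payload_conflict(addr, strand)) # embedded verbatim
  # the reverse complement is screened too: a poly-A address conflicts with
  # a poly-T payload, but not with an unrelated homopolymer
  expect_true(payload_conflict(strrep("A", 20), strrep("T", 30), 6))
  expect_false(payload_conflict(strrep("A", 20), strrep("G", 30), 6))
  withr::with_seed(19, {
    addrs <- random_dna(20, 20)
    strands <- random_dna(10, 60)
  })
  for (a in addrs) {
    d <- oracle_min_payload_distance(a, strands)
    expect_identical(payload_conflict(a, strands, 6), d < 6)
    expect_identical(payload_conflict(a, strands, 20), d < 20)
  }
})

test_that("the full-enumeration survey equals the brute-force oracle", {
  withr::with_seed(23, {
    cands <- random_dna(50, 20)
  })
  db <- make_survey_database(100, 6, seed = 23)
  for (mode in c("DORIS", "PCR")) {
    res <- monte_carlo_survey(
      length(cands), db, mode = mode, threshold = 6, seed = 23,
      payload_sample = Inf, L = 6, candidates = cands
    )
    expect_identical(res$survivor_addresses, oracle_survey(cands, db, mode, 6),
                     info = mode)
  }
})

test_that("overhang-mode survivors ignore the database; PCR survivors are a subset", {
  cands <- generate_address_candidates(150, seed = 31)
  db4 <- make_survey_database(60, 4, seed = 31)
  db12 <- make_survey_database(60, 12, seed = 32)
  d1 <- monte_carlo_survey(150, db4, "DORIS", seed = 31, L = 4,
                           candidates = cands)
  d2 <- monte_carlo_survey(150, db12, "DORIS", seed = 31, L = 12,
                           candidates = cands)
  expect_identical(d1$survivor_addresses, d2$survivor_addresses)
  p1 <- monte_carlo_survey(150, db4, "PCR", seed = 31, L = 4,
                           payload_sample = Inf, candidates = cands)
  expect_true(all(p1$survivor_addresses %in% d1$survivor_addresses))
  expect_lte(p1$survivors, d1$survivors)
  expect_error(monte_carlo_survey(10, character(0), "PCR"), "non-empty")
})

test_that("the capacity curve joins survivors with the analytic models", {
  curve <- capacity_curve(L_values = c(4L, 8L), mode = "DORIS",
                          n_candidates = 60, n_strands = 30, seed = 7,
                          payload_sample = 100)
  expect_identical(curve$survivors[1], curve$survivors[2])
  expect_equal(curve$density, density(c(4, 8)))
  expect_equal(curve$capacity, capacity(curve$survivors, curve$density))
  # denser encoding (smaller L), same survivors, more capacity
  expect_gt(curve$capacity[1], curve$capacity[2])
  empty <- capacity_curve(L_values = 4L, mode = "DORIS", n_candidates = 0,
                          n_strands = 10, seed = 7)
  expect_identical(empty$survivors, 0L)
  expect_equal(empty$capacity, 0)
})
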