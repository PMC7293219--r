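test_that("separation conserves copies exactly and is file specific", {
  db <- tiny_database(copies = 2000)
  before <- file_copy_counts(db)
  withr::with_seed(1, {
    out <- separate(db, revcomp(db$files$A$address))
  })
  after <- file_copy_counts(out$retained)
  bound <- sum(out$bound$strands$copies)
  expect_identical(sum(after) + bound, sum(before))
  expect_true(all(out$bound$strands$file == "A"))
  m <- compute_metrics(db, out$bound, out$retained)
  expect_equal(unname(m$file_specificity_pct["A"]), 100)
  expect_equal(unname(m$file_specificity_pct["B"]), 0)
  # roughly half of A is captured at the default probability
  expect_gt(bound / before[["A"]], 0.4)
  expect_lt(bound / before[["A"]], 0.6)
})

test_that("an internal binding site captures nothing in overhang mode but truncates in PCR mode", {
  layout <- template_layout()
  addrs <- withr::with_seed(2, {
    as.character(mutual_orthogonality_filter(random_dna(8, 20)))[1:2]
  })
  a <- addrs[1]
  b <- addrs[2]
  oligo_b <- revcomp(b)
  # payload carries an internal site complementary to oligo B'
  payload <- withr::with_seed(3, paste0(random_dna(1, 50), b, random_dna(1, 47)))
  tpl <- paste0(payload, default_promoter_region(), a)
  db <- storage_database(list(
    A = file_record(a, setNames(tpl, "A_001"), copies = 1000)
  ))
  withr::with_seed(4, {
    doris <- separate(db, oligo_b, mode = "DORIS")
    pcr <- separate(db, oligo_b, mode = "PCR")
  })
  expect_identical(sum(doris$bound$strands$copies), 0L)
  expect_gt(sum(pcr$bound$strands$copies), 0L)
  expect_gt(nrow(pcr$truncated), 0L)
  expect_true(all(pcr$truncated$product_length < nchar(tpl)))
  expect_true(all(pcr$truncated$site >= 1))
})

test_that("IVT yields scale with time while the bound file decays", {
  db <- tiny_database(copies = 5000)
  withr::with_seed(5, {
    sep <- separate(db, revcomp(db$files$A$address))
  })
  p0 <- access_params(ivt_hours = 0)
  out0 <- ivt(sep$bound, p0)
  expect_identical(nrow(out0$transcripts), 0L)
  expect_identical(out0$surviving_file$strands$copies,
                   sep$bound$strands$copies)
  hours <- c(2, 8, 16, 32)
  res <- lapply(hours, function(h) {
    withr::with_seed(6, {
      ivt(sep$bound, access_params(ivt_hours = h, ivt_loss_rate = 0.02))
    })
  })
  yields <- vapply(res, function(r) sum(r$transcripts$count), numeric(1))
  left <- vapply(res, function(r) sum(r$surviving_file$strands$copies),
                 numeric(1))
  expect_true(all(diff(yields) > 0))
  expect_true(all(diff(left) < 0))
  # transcript is the payload upstream of the promoter region
  expect_identical(nchar(res[[1]]$transcripts$sequence[1]), 117L)
})

test_that("returning a file honours the elution efficiency", {
  db <- tiny_database(copies = 3000)
  withr::with_seed(7, {
    sep <- separate(db, revcomp(db$files$A$address))
  })
  full <- withr::with_seed(8, {
    return_file(sep$retained, sep$bound, access_params(elution_efficiency = 1))
  })
  expect_identical(file_copy_counts(full), file_copy_counts(db))
  none <- withr::with_seed(8, {
    return_file(sep$retained, sep$bound, access_params(elution_efficiency = 0))
  })
  expect_identical(file_copy_counts(none), file_copy_counts(sep$retained))
  # Monte Carlo mean of returned copies matches the closed form
  bound_copies <- sum(sep$bound$strands$copies)
  eff <- 0.6
  p <- access_params(elution_efficiency = eff)
  means <- withr::with_seed(9, {
    vapply(seq_len(1000), function(i) {
      sum(file_copy_counts(return_file(sep$retained, sep$bound, p))) -
        sum(file_copy_counts(sep$retained))
    }, numeric(1))
  })
  expected <- bound_copies * eff
  se <- sqrt(bound_copies * eff * (1 - eff)) / sqrt(1000)
  expect_lt(abs(mean(means) - expected), 3 * se)
})

test_that("repeated access drains the accessed file geometrically and spares the rest", {
  db <- tiny_database(copies = 4000)
  params <- access_params()
  out <- repeat_access(db, db$files$A$address, 5, params, seed = 10)
  traj <- out$trajectory
  expect_identical(nrow(traj[traj$cycle == 0, ]), 3L)
  a5 <- traj$retention_pct[traj$cycle == 5 & traj$file == "A"]
  expect_gt(a5, 40)
  expect_lt(a5, 60)
  expect_equal(traj$retention_pct[traj$cycle == 5 & traj$file == "B"], 100)
  # n = 0 reports only the initial state
  out0 <- repeat_access(db, db$files$A$address, 0, params, seed = 10)
  expect_identical(unique(out0$trajectory$cycle), 0L)
  expect_identical(file_copy_counts(out0$db), file_copy_counts(db))
})

test_that("metrics handle degenerate inputs as undefined, not zero", {
  db <- tiny_database(copies = 100)
  empty_sample <- structure(
    list(address = db$files$A$address,
         strands = db$files$A$strands[0, ]),
    class = "file_record"
  )
  m <- compute_metrics(db, empty_sample, db)
  expect_true(all(is.na(m$file_specificity_pct)))
  expect_equal(unname(m$separation_efficiency_pct), c(0, 0, 0))
  expect_equal(unname(m$retention_rate_pct), c(100, 100, 100))
  expect_true(all(m$normalized_abundance == 1))
})

test_that("the calibrated access parameters compose to the per-cycle retention", {
  p <- access_params()
  s <- (1 - p$ivt_loss_rate)^p$ivt_hours * p$elution_efficiency
  r <- (1 - p$separation_probability) + p$separation_probability * s
  expect_equal(r, p$per_access_retention)
  expect_error(access_params(separation_probability = 0.1,
                             per_access_retention = 0.5),
               "unreachable")
})
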