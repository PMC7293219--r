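make_locked_db <- function(add_temperature = 98, copies = 1000, seed = 1) {
  db <- tiny_database(copies = copies)
  lock <- make_lock(db$files$A$address, seed = seed)
  db$files$A <- withr::with_seed(seed, {
    lock_file(db$files$A, lock, add_temperature_celsius = add_temperature)
  })
  list(db = db, lock = lock)
}

test_that("locking buries the address and records the 30 nt toehold", {
  x <- make_locked_db()
  rows <- x$db$files$A$strands
  expect_true(all(rows$state == "LOCKED"))
  expect_true(all(rows$lock_toehold == 30L))
  expect_identical(nchar(x$lock), 50L)
  withr::with_seed(2, {
    sep <- separate(x$db, revcomp(x$db$files$A$address))
  })
  expect_identical(sum(sep$bound$strands$copies), 0L)
})

test_that("heat melts the lock; a key removes it at room temperature", {
  x <- make_locked_db()
  withr::with_seed(3, {
    hot <- separate(x$db, revcomp(x$db$files$A$address),
                    temperature_celsius = 75)
  })
  expect_gt(sum(hot$bound$strands$copies), 0L)
  db <- x$db
  db$files$A <- unlock_file(db$files$A, make_key(x$lock))
  expect_true(all(db$files$A$strands$state == "EXPOSED"))
  withr::with_seed(3, {
    cold <- separate(db, revcomp(db$files$A$address))
  })
  # unlocked capture matches the no-lock level under the same draws
  ref <- withr::with_seed(3, {
    separate(tiny_database(copies = 1000), revcomp(db$files$A$address))
  })
  expect_identical(sum(cold$bound$strands$copies),
                   sum(ref$bound$strands$copies))
})

test_that("a wrong key leaves the file locked; lock/unlock cycles are idempotent", {
  x <- make_locked_db()
  wrong <- withr::with_seed(9, random_dna(1, 50))
  expect_warning(f <- unlock_file(x$db$files$A, wrong), "stays locked")
  expect_true(all(f$strands$state == "LOCKED"))
  f <- unlock_file(f, make_key(x$lock))
  f <- withr::with_seed(4, lock_file(f, x$lock))
  f <- unlock_file(f, make_key(x$lock))
  expect_true(all(f$strands$state == "EXPOSED"))
  expect_identical(sum(f$strands$copies), 1000L)
})

test_that("adding the lock cold is leaky; adding it at 45 C or above is not", {
  leaky <- make_locked_db(add_temperature = 25, copies = 5000, seed = 7)
  states <- leaky$db$files$A$strands
  expect_setequal(unique(states$state), c("LOCKED", "EXPOSED"))
  leak <- sum(states$copies[states$state == "EXPOSED"])
  expect_gt(leak, 0L)
  expect_lt(leak / sum(states$copies), 0.15)
  tight <- make_locked_db(add_temperature = 45, copies = 5000, seed = 7)
  expect_true(all(tight$db$files$A$strands$state == "LOCKED"))
  expect_error(lock_file(tiny_database()$files$A, strrep("A", 50)),
               "lacks the 20 nt complement")
})

test_that("renaming redirects capture to the new address only", {
  db <- tiny_database(copies = 1000)
  a <- db$files$A$address
  b <- db$files$B$address
  c_ <- db$files$C$address
  db$files$A <- rename_file(db$files$A, make_rename_oligo(a, b))
  expect_true(all(db$files$A$strands$state == "RENAMED"))
  withr::with_seed(5, {
    by_b <- separate(db, revcomp(b))
    by_a <- separate(db, revcomp(a))
    by_c <- separate(db, revcomp(c_))
  })
  expect_true("A" %in% by_b$bound$strands$file) # renamed file answers to B'
  expect_false("A" %in% by_a$bound$strands$file)
  expect_false("A" %in% by_c$bound$strands$file)
  # the symmetric rename works the same way
  db2 <- tiny_database(copies = 1000)
  db2$files$A <- rename_file(db2$files$A,
                             make_rename_oligo(db2$files$A$address, c_))
  withr::with_seed(6, {
    by_c2 <- separate(db2, revcomp(c_))
  })
  expect_true("A" %in% by_c2$bound$strands$file)
  expect_error(rename_file(db$files$B, make_rename_oligo(a, b)),
               "lacks the complement")
  expect_error(rename_file(db$files$B, strrep("A", 20)), "40 nt")
})

test_that("deletion blocks the overhang for every oligo and is terminal", {
  db <- tiny_database(copies = 1000)
  a <- db$files$A$address
  db$files$A <- delete_file(db$files$A, revcomp(a))
  expect_true(all(db$files$A$strands$state == "BLOCKED"))
  for (addr in c(a, db$files$B$address, db$files$C$address)) {
    withr::with_seed(7, {
      sep <- separate(db, revcomp(addr))
    })
    expect_false("A" %in% sep$bound$strands$file)
  }
  expect_error(rename_file(db$files$A,
                           make_rename_oligo(a, db$files$B$address)),
               "no exposed toehold")
  empty <- file_record(a, character(0))
  expect_identical(nrow(delete_file(empty, revcomp(a))$strands), 0L)
  expect_error(delete_file(db$files$B, revcomp(a)), "not the complement")
})

test_that("the scripted-operations runner replays a lock/unlock/access cycle", {
  db <- tiny_database(copies = 1000)
  lock <- make_lock(db$files$A$address, seed = 3)
  script <- list(
    list(op = "lock", file = "A", lock = lock),
    list(op = "separate", oligo = revcomp(db$files$A$address)),
    list(op = "metrics"),
    list(op = "unlock", file = "A", key = make_key(lock)),
    list(op = "separate", oligo = revcomp(db$files$A$address)),
    list(op = "ivt"),
    list(op = "return"),
    list(op = "metrics")
  )
  out <- run_ops_script(db, script, seed = 12)
  expect_identical(out$report[[2]]$result$captured, 0L) # locked: no capture
  expect_gt(out$report[[5]]$result$captured, 0L)        # unlocked: captured
  m <- out$report[[8]]$result
  expect_s3_class(m, "metrics_report")
  expect_gt(m$retention_rate_pct[["A"]], 70)
  expect_equal(m$retention_rate_pct[["B"]], 100)
  # replays are exact
  out2 <- run_ops_script(db, script, seed = 12)
  expect_identical(file_copy_counts(out$db), file_copy_counts(out2$db))
})

test_that("the printed molar ratios are exposed as configuration", {
  mr <- molar_ratios()
  expect_equal(unname(mr$lock_unlock), c(1, 10, 10, 15))
  expect_equal(unname(mr$rename), c(1, 10, 15))
})
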