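pool <- build_variant_pool(seed = 1)

test_that("the variant pool enumerates every 5-mer and 3-mer exactly once", {
  tab <- pool$variant_table
  expect_identical(nrow(tab), 1088L)
  up <- tab[tab$class == "UPSTREAM_5", ]
  down <- tab[tab$class == "DOWNSTREAM_3", ]
  expect_identical(nrow(up), 1024L)
  expect_identical(nrow(down), 64L)
  expect_setequal(up$variant, dorisim:::all_kmers(5))
  expect_setequal(down$variant, dorisim:::all_kmers(3))
  expect_false(anyDuplicated(tab$template) > 0)
  expect_true(all(nchar(tab$template) == 160L))
  # barcodes: distinct, pairwise Hamming distance >= 3
  expect_false(anyDuplicated(tab$barcode) > 0)
  bc <- withr::with_seed(2, sample(tab$barcode, 30))
  min_d <- min(vapply(bc, function(b) {
    others <- setdiff(tab$barcode, b)
    min(vapply(others, oracle_hamming, numeric(1), a = b))
  }, numeric(1)))
  expect_gte(min_d, 3)
  # deterministic per seed
  expect_identical(build_variant_pool(seed = 1)$variant_table$template,
                   tab$template)
  # the variant really sits at its stated locus
  expect_identical(substr(up$template[5], 141, 145), up$variant[5])
  expect_identical(substr(down$template[5], 115, 117), down$variant[5])
})

test_that("error-free reads match their templates and demultiplex perfectly", {
  rs <- simulate_reads(pool, 500, seed = 3)
  tab <- pool$variant_table
  expect_true(all(rs$reads == tab$template[match(rs$truth, tab$variant_id)]))
  dm <- demultiplex(rs, pool)
  expect_identical(dm$unassigned, 0L)
  expect_identical(unname(dm$counts[rs$truth[1]]),
                   sum(rs$truth == rs$truth[1]))
  expect_identical(sum(dm$counts), 500L)
})

test_that("barcode assignment tolerates one mismatch and sends ambiguous reads to the unassigned bin", {
  tab <- pool$variant_table
  # a single substitution anywhere in the barcode still assigns uniquely
  withr::with_seed(4, {
    picks <- sample(nrow(tab), 20)
  })
  for (i in picks) {
    read <- tab$template[i]
    pos <- ((i * 7) %% pool$barcode_length) + 1L
    old <- substr(read, pos, pos)
    substr(read, pos, pos) <- setdiff(c("A", "C", "G", "T"), old)[1]
    expect_identical(demultiplex(read, pool)$assignment, tab$variant_id[i])
  }
  # an observed barcode equidistant between two true barcodes is a tie and
  # lands in the unassigned bin
  bcs <- tab$barcode[1:100]
  found <- FALSE
  for (i in seq_along(bcs)) {
    for (j in seq_len(i - 1L)) {
      if (hamming_distance(bcs[i], bcs[j]) != 4L) next
      diffpos <- which(strsplit(bcs[i], "")[[1]] != strsplit(bcs[j], "")[[1]])
      obs <- bcs[i]
      for (pos in diffpos[1:2]) {
        substr(obs, pos, pos) <- substr(bcs[j], pos, pos)
      }
      d_all <- vapply(tab$barcode, hamming_distance, integer(1), b = obs)
      if (min(d_all) == 2L && sum(d_all == 2L) >= 2L) {
        read2 <- tab$template[i]
        substr(read2, 1, pool$barcode_length) <- obs
        dm2 <- demultiplex(read2, pool)
        expect_true(is.na(dm2$assignment))
        expect_identical(dm2$unassigned, 1L)
        found <- TRUE
      }
      if (found) break
    }
    if (found) break
  }
  expect_true(found) # the pool contains such an ambiguous neighbourhood
})

test_that("normalized abundance is the elementwise post/pre ratio", {
  pre <- c(v1 = 10, v2 = 20, v3 = 0)
  post <- c(v1 = 10, v2 = 40, v3 = 5)
  na_ <- normalized_abundance(post, pre)
  expect_equal(unname(na_[c("v1", "v2")]), c(1, 2))
  expect_true(is.na(na_[["v3"]]))
  withr::with_seed(5, {
    pre_r <- setNames(rpois(50, 100) + 1, sprintf("x%02d", 1:50))
    post_r <- setNames(rpois(50, 100), names(pre_r))
  })
  expect_equal(unname(normalized_abundance(post_r, pre_r)),
               unname(post_r / pre_r))
})

test_that("the read pipeline recovers a known efficiency map", {
  tab <- pool$variant_table
  eff <- setNames(rep(1, nrow(tab)), tab$variant_id)
  boosted <- withr::with_seed(6, sample(tab$variant_id, 100))
  eff[boosted] <- 2
  pre <- simulate_reads(pool, 2e5, provenance = "pre_library", seed = 7)
  post <- simulate_reads(pool, 2e5, efficiency = eff, seed = 8)
  ab <- normalized_abundance(demultiplex(post, pool)$counts,
                             demultiplex(pre, pool)$counts)
  ratio <- mean(ab[boosted], na.rm = TRUE) /
    mean(ab[setdiff(tab$variant_id, boosted)], na.rm = TRUE)
  expect_gt(ratio, 1.8)
  expect_lt(ratio, 2.2)
  # rank agreement between injected efficiency and estimated abundance
  expect_gt(suppressWarnings(cor(eff[names(ab)], ab, method = "spearman",
                                 use = "complete.obs")), 0.5)
})

test_that("quartile groups are balanced and PFM columns are probability simplices", {
  expect_identical(dorisim:::quartile_sizes(1088L), rep(272L, 4L))
  expect_identical(sum(dorisim:::quartile_sizes(1086L)), 1086L)
  expect_lte(diff(range(dorisim:::quartile_sizes(1086L))), 1L)
  tab <- pool$variant_table
  ab <- withr::with_seed(9, {
    setNames(runif(nrow(tab)), tab$variant_id)
  })
  pfms <- quartile_pfms(ab, pool)
  expect_named(pfms, c("UPSTREAM_5", "DOWNSTREAM_3"))
  expect_length(pfms$UPSTREAM_5, 4L)
  for (m in pfms$UPSTREAM_5) {
    expect_identical(dim(m), c(4L, 5L))
    expect_equal(unname(colSums(m)), rep(1, 5))
  }
  for (m in pfms$DOWNSTREAM_3) expect_identical(dim(m), c(4L, 3L))
  # a quartile of identical sequences gives unit-vector columns
  mini <- pool
  keep <- tab$class == "DOWNSTREAM_3"
  ab_equal <- setNames(rep(1, 64), tab$variant_id[keep])
  # ties broken lexicographically: Q1 holds the 16 lexicographically first
  pfms2 <- quartile_pfms(ab_equal, mini)$DOWNSTREAM_3
  q1_seqs <- sort(tab$variant[keep])[1:16]
  expect_equal(unname(pfms2[[1]]["A", 1]),
               mean(substr(q1_seqs, 1, 1) == "A"))
})

test_that("A/T-content grouping finds injected shifts and not null ones", {
  tab <- pool$variant_table
  up <- tab[tab$class == "UPSTREAM_5", ]
  expect_equal(unique(round(100 * nchar(gsub("[CG]", "", "ATATA")) / 5)), 100)
  null_ab <- withr::with_seed(10, {
    setNames(rnorm(nrow(tab), 10, 1), tab$variant_id)
  })
  res0 <- at_content_groups(null_ab, pool, "UPSTREAM_5")
  expect_gt(res0$anova$p, 0.001)
  shifted <- null_ab
  at100 <- up$variant_id[!grepl("[CG]", up$variant)]
  shifted[at100] <- shifted[at100] + 10
  res1 <- at_content_groups(shifted, pool, "UPSTREAM_5")
  expect_lt(res1$anova$p, 1e-6)
  hits <- res1$tukey[grepl("100", res1$tukey$comparison), ]
  expect_true(all(hits$p_adj < 0.01))
  # the bucket labels are the A/T percentages
  expect_setequal(unique(res1$groups$at_pct), c(0, 20, 40, 60, 80, 100))
})

test_that("per-position error rates recover hand-built and injected errors", {
  tab <- pool$variant_table
  clean <- rep(tab$template[1], 10)
  truth <- rep(tab$variant_id[1], 10)
  zero <- per_position_error_rates(clean, pool, assignment = truth)
  expect_true(all(zero$counts == 0L))
  expect_true(all(zero$rates == 0))
  # one substitution at position 50 in 1 of 10 reads -> rate 0.1 there
  dirty <- clean
  old <- substr(dirty[1], 50, 50)
  substr(dirty[1], 50, 50) <- setdiff(c("A", "C", "G", "T"), old)[1]
  one <- per_position_error_rates(dirty, pool, assignment = truth)
  expect_equal(unname(one$rates[50, "sub"]), 0.1)
  expect_equal(sum(one$counts), 1L)
  # a deletion and an insertion are charged to their positions
  indel <- clean
  indel[2] <- paste0(substr(indel[2], 1, 79), substr(indel[2], 81, 160))
  two <- per_position_error_rates(indel, pool, assignment = truth)
  expect_equal(sum(two$counts[, "del"]), 1L)
  expect_equal(sum(two$counts), 1L)
})

test_that("edit-distance alignment agrees with utils::adist", {
  ref <- pool$variant_table$template[3]
  reads <- withr::with_seed(11, {
    simulate_reads(pool, 60,
                   error_profile = list(sub = 0.02, ins = 0.005, del = 0.005),
                   seed = 12)$reads[1:30]
  })
  ev <- dorisim:::error_events_cpp(reads, ref)
  expect_identical(ev$distance, as.integer(adist(reads, ref)))
})
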