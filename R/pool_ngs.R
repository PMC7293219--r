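## T7 promoter-variant pool: 1024 strands carrying every 5-mer immediately
## upstream of the promoter (in the single-stranded overhang) plus 64 strands
## carrying every 3-mer immediately downstream (payload side), each tagged by
## a payload barcode. Synthetic IVT-RT-PCR-NGS reads are drawn from the pool
## and pushed through the readout analyses: normalized abundance, quartile
## position-frequency matrices, A/T-content groups, per-position error rates.

## barcodes with pairwise Hamming distance >= 3 (so any single read error is
## uniquely correctable at the <=1-mismatch assignment rule): seeded random
## candidates packed greedily until n survive
make_barcodes <- function(n, barcode_length = 10L, seed = 1L) {
  cands <- withr::with_seed(seed, {
    unique(random_dna(40L * n + 5000L, barcode_length))
  })
  keep <- greedy_orthogonal_cpp(cands, 3L, check_revcomp = FALSE)
  out <- cands[keep]
  if (length(out) < n) stop("barcode space exhausted")
  out[seq_len(n)]
}

all_kmers <- function(k) {
  bases <- c("A", "C", "G", "T")
  do.call(paste0, expand.grid(rep(list(bases), k),
                              stringsAsFactors = FALSE)[, k:1, drop = FALSE])
}

#' Build the promoter-variant pool
#'
#' 1024 strands enumerate every 5 nt variant immediately upstream of the
#' promoter region (the first 5 nt of the single-stranded address overhang,
#' class `UPSTREAM_5`) and 64 strands every 3 nt variant immediately
#' downstream (the last 3 payload nt before the promoter, class
#' `DOWNSTREAM_3`): 1088 distinct 160 nt templates in total. Each strand
#' carries a barcode at the start of its payload identifying its variant;
#' barcodes have pairwise Hamming distance >= 3 so a single read error still
#' assigns uniquely under the one-mismatch demultiplexing rule.
#'
#' @param layout A [template_layout()] (default 160 nt).
#' @param barcode_length Barcode length in nt (default 10).
#' @param seed RNG seed fixing the scaffold payload and base address.
#' @return An object of class `variant_pool`: list with `variant_table` (data
#'   frame `variant_id`, `class`, `variant`, `barcode`, `template`),
#'   `layout`, `promoter`, `barcode_length`.
#' @export
build_variant_pool <- function(layout = template_layout(),
                               barcode_length = 10L, seed = 1L) {
  stopifnot(inherits(layout, "template_layout"))
  promoter <- default_promoter_region()
  up <- all_kmers(5L)   # 1024
  down <- all_kmers(3L) # 64
  n_total <- length(up) + length(down)
  barcodes <- make_barcodes(n_total, barcode_length,
                            seed = derive_seed(seed, "barcodes"))
  payload_len <- layout$payload[2] - layout$payload[1]
  stopifnot(payload_len >= barcode_length + 3L)
  scaffold <- withr::with_seed(seed, list(
    payload = random_dna(1L, payload_len),
    address = random_dna(1L, layout$address_length)
  ))
  base_payload <- scaffold$payload
  base_address <- scaffold$address
  mk_payload <- function(barcode, down3 = NULL) {
    p <- base_payload
    substr(p, 1L, barcode_length) <- barcode
    if (!is.null(down3)) substr(p, payload_len - 2L, payload_len) <- down3
    p
  }
  up_templates <- vapply(seq_along(up), function(i) {
    addr <- base_address
    substr(addr, 1L, 5L) <- up[i]
    paste0(mk_payload(barcodes[i]), promoter, addr)
  }, character(1))
  down_templates <- vapply(seq_along(down), function(i) {
    paste0(mk_payload(barcodes[length(up) + i], down[i]), promoter,
           base_address)
  }, character(1))
  tab <- data.frame(
    variant_id = c(sprintf("up_%s", up), sprintf("down_%s", down)),
    class = rep(c("UPSTREAM_5", "DOWNSTREAM_3"), c(length(up), length(down))),
    variant = c(up, down),
    barcode = barcodes,
    template = c(up_templates, down_templates),
    stringsAsFactors = FALSE
  )
  stopifnot(!anyDuplicated(tab$template))
  structure(
    list(variant_table = tab, layout = layout, promoter = promoter,
         barcode_length = as.integer(barcode_length), seed = seed),
    class = "variant_pool"
  )
}

#' @export
print.variant_pool <- function(x, ...) {
  cat(sprintf(
    "variant_pool: %d strands (%d upstream 5-mers + %d downstream 3-mers), %d nt\n",
    nrow(x$variant_table), sum(x$variant_table$class == "UPSTREAM_5"),
    sum(x$variant_table$class == "DOWNSTREAM_3"), x$layout$total_length
  ))
  invisible(x)
}

## inject substitution / insertion / deletion errors into reads
inject_errors <- function(reads, error_profile) {
  sub <- error_profile$sub %||% 0
  ins <- error_profile$ins %||% 0
  del <- error_profile$del %||% 0
  if (sub == 0 && ins == 0 && del == 0) return(reads)
  bases <- c("A", "C", "G", "T")
  out <- reads
  if (sub > 0) {
    width <- nchar(out)
    chars <- strsplit(out, "", fixed = TRUE)
    out <- vapply(seq_along(chars), function(i) {
      x <- chars[[i]]
      hit <- which(runif(length(x)) < sub)
      if (length(hit)) {
        cur <- match(x[hit], bases) - 1L
        x[hit] <- bases[((cur + sample(1:3, length(hit), replace = TRUE)) %%
                           4L) + 1L]
      }
      paste(x, collapse = "")
    }, character(1))
  }
  if (ins > 0 || del > 0) {
    n_ins <- rbinom(length(out), nchar(out), ins)
    n_del <- rbinom(length(out), nchar(out), del)
    touch <- which(n_ins > 0L | n_del > 0L)
    for (i in touch) {
      x <- strsplit(out[i], "", fixed = TRUE)[[1L]]
      if (n_del[i] > 0L && length(x) > n_del[i]) {
        x <- x[-sample(length(x), n_del[i])]
      }
      if (n_ins[i] > 0L) {
        at <- sort(sample(length(x) + 1L, n_ins[i], replace = TRUE))
        ins_bases <- sample(bases, n_ins[i], replace = TRUE)
        for (k in seq_along(at)) {
          pos <- at[k] + k - 1L
          x <- append(x, ins_bases[k], after = pos - 1L)
        }
      }
      out[i] <- paste(x, collapse = "")
    }
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulate sequencing reads from the pool
#'
#' Reads are drawn multinomially across variants with weights proportional to
#' abundance (provenance `"pre_library"`) or abundance x relative
#' transcription efficiency (provenance `"post_ivt"`), then per-base
#' substitution / insertion / deletion errors are injected at the stated
#' rates.
#'
#' @param pool A [build_variant_pool()] pool.
#' @param n_reads Number of reads to draw.
#' @param efficiency Named numeric vector (by `variant_id`) of relative
#'   transcription efficiencies; `NULL` = uniform.
#' @param abundance Named numeric vector of library abundances; `NULL` =
#'   uniform.
#' @param error_profile List with elements `sub`, `ins`, `del` (per-base
#'   rates, default all 0).
#' @param provenance `"post_ivt"` or `"pre_library"`.
#' @param seed RNG seed.
#' @return An object of class `read_set`: list with `reads` (character),
#'   `truth` (variant_id per read), `provenance`, `error_profile`, `seed`.
#' @export
simulate_reads <- function(pool, n_reads, efficiency = NULL,
                           abundance = NULL,
                           error_profile = list(sub = 0, ins = 0, del = 0),
                           provenance = c("post_ivt", "pre_library"),
                           seed = 1L) {
  stopifnot(inherits(pool, "variant_pool"), n_reads >= 0)
  provenance <- match.arg(provenance)
  tab <- pool$variant_table
  w <- rep(1, nrow(tab))
  if (!is.null(abundance)) {
    stopifnot(all(tab$variant_id %in% names(abundance)))
    w <- w * abundance[tab$variant_id]
  }
  if (provenance == "post_ivt" && !is.null(efficiency)) {
    stopifnot(all(tab$variant_id %in% names(efficiency)),
              all(efficiency >= 0))
    w <- w * efficiency[tab$variant_id]
  }
  if (sum(w) <= 0) stop("all sampling weights are zero")
  withr::with_seed(seed, {
    counts <- as.integer(rmultinom(1L, n_reads, w))
    reads <- rep(tab$template, counts)
    truth <- rep(tab$variant_id, counts)
    reads <- inject_errors(reads, error_profile)
  })
  structure(
    list(reads = reads, truth = truth, provenance = provenance,
         error_profile = error_profile, seed = seed),
    class = "read_set"
  )
}

#' Write a read set to FASTQ (placeholder qualities)
#' @param read_set A [simulate_reads()] result.
#' @param path Output FASTQ path.
#' @return Invisibly `path`.
#' @export
write_fastq <- function(read_set, path) {
  stopifnot(inherits(read_set, "read_set"))
  ids <- sprintf("@read%06d truth=%s", seq_along(read_set$reads),
                 read_set$truth)
  qual <- strrep("I", nchar(read_set$reads))
  writeLines(rbind(ids, read_set$reads, "+", qual), path)
  invisible(path)
}

#' Assign reads to pool variants via their barcodes
#'
#' The barcode locus (start of the payload) is excised from each read and
#' matched against the pool's barcode table: a read is assigned to the unique
#' barcode within Hamming distance `max_mismatch` (default 1); reads with no
#' such barcode, or tied between several, land in the unassigned bin.
#'
#' @param reads A `read_set` or character vector of reads.
#' @param pool The `variant_pool`.
#' @param max_mismatch Maximum barcode Hamming distance (default 1).
#' @return List: `counts` (named integer per variant_id, zeros kept),
#'   `unassigned` (count), `assignment` (variant_id or `NA` per read).
#' @export
demultiplex <- function(reads, pool, max_mismatch = 1L) {
  stopifnot(inherits(pool, "variant_pool"))
  if (inherits(reads, "read_set")) reads <- reads$reads
  tab <- pool$variant_table
  bl <- pool$barcode_length
  obs <- substr(reads, 1L, bl)
  assignment <- tab$variant_id[match(obs, tab$barcode)]
  todo <- which(is.na(assignment) & nchar(obs) == bl)
  if (length(todo) > 0L && max_mismatch > 0L) {
    bc_mat <- do.call(rbind, strsplit(tab$barcode, "", fixed = TRUE))
    for (i in todo) {
      o <- strsplit(obs[i], "", fixed = TRUE)[[1L]]
      d <- rowSums(bc_mat != matrix(o, nrow(bc_mat), bl, byrow = TRUE))
      dm <- min(d)
      if (dm <= max_mismatch && sum(d == dm) == 1L) {
        assignment[i] <- tab$variant_id[which.min(d)]
      }
    }
  }
  counts <- table(factor(assignment, levels = tab$variant_id))
  list(counts = setNames(as.integer(counts), tab$variant_id),
       unassigned = sum(is.na(assignment)),
       assignment = assignment)
}

#' Normalized abundance (post / pre read-count ratio)
#'
#' Per-variant read count after IVT-RT-PCR-sequencing divided by its count in
#' the original library sample. Undefined (NA) where the pre count is zero.
#'
#' @param post_counts,pre_counts Named numeric vectors over the same variant
#'   universe.
#' @return Named numeric vector of ratios.
#' @export
normalized_abundance <- function(post_counts, pre_counts) {
  stopifnot(setequal(names(post_counts), names(pre_counts)))
  pre <- pre_counts[names(post_counts)]
  ifelse(pre > 0, post_counts / pre, NA_real_)
}

## split indices 1..n into 4 groups whose sizes differ by at most 1
quartile_sizes <- function(n) {
  base <- n %/% 4L
  extra <- n %% 4L
  base + as.integer(seq_len(4L) <= extra)
}

#' Quartile position-frequency matrices of the variant positions
#'
#' Variants of each class are ranked by normalized abundance (ascending;
#' quartile 1 = lowest, quartile 4 = highest; ties broken by variant sequence
#' lexicographically), split into four groups of near-equal size, and each
#' group is summarised as a position x base frequency matrix over the variant
#' positions — the standard input for a sequence-logo renderer.
#'
#' @param abundances Named numeric vector (by `variant_id`); NAs dropped.
#' @param pool The `variant_pool`.
#' @return Named list per class; each element a list of 4 matrices (rows
#'   A/C/G/T, one column per variant position, columns summing to 1) ordered
#'   quartile 1 (lowest abundance) to 4 (highest).
#' @export
quartile_pfms <- function(abundances, pool) {
  stopifnot(inherits(pool, "variant_pool"))
  tab <- pool$variant_table
  out <- list()
  for (cl in unique(tab$class)) {
    sub <- tab[tab$class == cl, ]
    ab <- abundances[sub$variant_id]
    keep <- !is.na(ab)
    sub <- sub[keep, ]
    ab <- ab[keep]
    if (nrow(sub) < 4L) next # class not represented in these abundances
    ord <- order(ab, sub$variant)
    sub <- sub[ord, ]
    sizes <- quartile_sizes(nrow(sub))
    grp <- rep(seq_len(4L), sizes)
    out[[cl]] <- lapply(seq_len(4L), function(q) {
      seqs <- sub$variant[grp == q]
      m <- do.call(rbind, strsplit(seqs, "", fixed = TRUE))
      pfm <- vapply(seq_len(ncol(m)), function(j) {
        tabulate(match(m[, j], c("A", "C", "G", "T")), 4L) / nrow(m)
      }, numeric(4L))
      rownames(pfm) <- c("A", "C", "G", "T")
      colnames(pfm) <- sprintf("pos%d", seq_len(ncol(m)))
      pfm
    })
  }
  if (length(out) == 0L) stop("need at least 4 variants with abundances")
  out
}

#' Group abundances by A/T content of the variant positions
#'
#' Buckets each variant by the A/T percentage of its variant positions
#' (0/20/.../100% for 5-mers, 0/33/67/100% for 3-mers), then tests for
#' abundance differences between buckets with one-way ANOVA and Tukey-Kramer
#' pairwise comparisons. Buckets with fewer than 2 members are dropped from
#' the test (with a message).
#'
#' @param abundances Named numeric vector (by `variant_id`).
#' @param pool The `variant_pool`.
#' @param class `"UPSTREAM_5"` or `"DOWNSTREAM_3"`.
#' @return List: `groups` (data frame `variant_id`, `at_pct`, `abundance`),
#'   `anova` (`F`, `p`), `tukey` (data frame of pairwise comparisons with
#'   adjusted p values).
#' @export
at_content_groups <- function(abundances, pool,
                              class = c("UPSTREAM_5", "DOWNSTREAM_3")) {
  stopifnot(inherits(pool, "variant_pool"))
  class <- match.arg(class)
  sub <- pool$variant_table[pool$variant_table$class == class, ]
  ab <- abundances[sub$variant_id]
  keep <- !is.na(ab)
  sub <- sub[keep, ]
  ab <- unname(ab[keep])
  k <- nchar(sub$variant[1L])
  at <- nchar(gsub("[CG]", "", sub$variant)) / k
  at_pct <- round(100 * at)
  groups <- data.frame(variant_id = sub$variant_id, at_pct = at_pct,
                       abundance = ab, stringsAsFactors = FALSE)
  sizes <- table(at_pct)
  usable <- names(sizes)[sizes >= 2L]
  if (length(usable) < length(sizes)) {
    message("dropping A/T groups with < 2 members: ",
            paste(setdiff(names(sizes), usable), collapse = ", "))
  }
  if (length(usable) < 2L) {
    return(list(groups = groups, anova = list(F = NA_real_, p = NA_real_),
                tukey = NULL))
  }
  dat <- groups[groups$at_pct %in% as.numeric(usable), ]
  dat$grp <- factor(dat$at_pct)
  fit <- aov(abundance ~ grp, data = dat)
  s <- summary(fit)[[1L]]
  tk <- TukeyHSD(fit)$grp
  tukey <- data.frame(
    comparison = rownames(tk), diff = tk[, "diff"],
    p_adj = tk[, "p adj"], row.names = NULL, stringsAsFactors = FALSE
  )
  list(groups = groups,
       anova = list(F = s[["F value"]][1L], p = s[["Pr(>F)"]][1L]),
       tukey = tukey)
}

#' Per-position sequencing error rates against the pool references
#'
#' Reads are assigned to variants by barcode, globally aligned to their
#' reference template by minimum edit distance (unit costs, deterministic
#' reference-leftmost indel placement), and substitution / insertion /
#' deletion events are tallied per reference position. The rate at a position
#' is events / aligned reads. Unassignable reads are excluded and counted.
#'
#' @param reads A `read_set` or character vector.
#' @param pool The `variant_pool`.
#' @param max_mismatch Barcode mismatch tolerance for assignment.
#' @param assignment Optional explicit per-read variant_id vector (`NA` =
#'   unassigned), bypassing barcode demultiplexing. Useful in validation
#'   studies where the generating variant is known: demultiplexing excludes
#'   reads whose barcode itself is corrupted, which deflates apparent error
#'   rates at the barcode locus.
#' @return List: `rates` (positions x 3 matrix, columns sub/ins/del),
#'   `counts` (same shape, raw event counts), `n_reads` (aligned reads),
#'   `n_unassigned`.
#' @export
per_position_error_rates <- function(reads, pool, max_mismatch = 1L,
                                     assignment = NULL) {
  stopifnot(inherits(pool, "variant_pool"))
  rs <- if (inherits(reads, "read_set")) reads$reads else reads
  dm <- if (is.null(assignment)) {
    demultiplex(rs, pool, max_mismatch)
  } else {
    stopifnot(length(assignment) == length(rs))
    list(assignment = assignment, unassigned = sum(is.na(assignment)))
  }
  tab <- pool$variant_table
  len <- pool$layout$total_length
  counts <- matrix(0L, nrow = len, ncol = 3L,
                   dimnames = list(NULL, c("sub", "ins", "del")))
  n_aligned <- 0L
  for (vid in unique(dm$assignment[!is.na(dm$assignment)])) {
    idx <- which(!is.na(dm$assignment) & dm$assignment == vid)
    ref <- tab$template[tab$variant_id == vid]
    ev <- error_events_cpp(rs[idx], ref)
    counts[, "sub"] <- counts[, "sub"] + ev$sub
    counts[, "ins"] <- counts[, "ins"] + ev$ins
    counts[, "del"] <- counts[, "del"] + ev$del
    n_aligned <- n_aligned + length(idx)
  }
  rates <- if (n_aligned > 0L) counts / n_aligned else counts * NA_real_
  list(rates = rates, counts = counts, n_reads = n_aligned,
       n_unassigned = dm$unassigned)
}
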