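# Independent oracles used to cross-check the package's fast paths.
# They are written against different machinery (Biostrings, utils::adist,
# character-level loops) than the implementation they verify.

# reverse complement via Biostrings
oracle_revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# per-position mismatch count from split characters
oracle_hamming <- function(a, b) {
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

# exhaustive sliding-window minimum Hamming distance of an address (either
# orientation) against every window of every strand (either orientation)
oracle_min_payload_distance <- function(address, strands) {
  w <- nchar(address)
  queries <- c(address, oracle_revcomp(address))
  best <- Inf
  for (s in c(strands, oracle_revcomp(strands))) {
    for (i in seq_len(nchar(s) - w + 1L)) {
      win <- substr(s, i, i + w - 1L)
      for (q in queries) best <- min(best, oracle_hamming(q, win))
    }
  }
  best
}

# greedy accept-in-order orthogonality filter, all-pairs character loops
oracle_greedy_filter <- function(candidates, threshold) {
  accepted <- character(0)
  keep <- logical(length(candidates))
  for (i in seq_along(candidates)) {
    ok <- TRUE
    for (a in accepted) {
      if (oracle_hamming(candidates[i], a) < threshold ||
          oracle_hamming(candidates[i], oracle_revcomp(a)) < threshold) {
        ok <- FALSE
        break
      }
    }
    keep[i] <- ok
    if (ok) accepted <- c(accepted, candidates[i])
  }
  candidates[keep]
}

# full brute-force survey: mutual orthogonality then (PCR only) the window
# scan over every database strand
oracle_survey <- function(candidates, database, mode, threshold) {
  surv <- oracle_greedy_filter(candidates, threshold)
  if (mode == "PCR") {
    conflict <- vapply(surv, function(a) {
      oracle_min_payload_distance(a, database) < threshold
    }, logical(1))
    surv <- surv[!conflict]
  }
  unname(surv)
}

# a tiny exposed test database with n_files one-strand files
tiny_database <- function(n_files = 3, copies = 1000, seed = 42) {
  addrs <- withr::with_seed(seed, {
    as.character(mutual_orthogonality_filter(random_dna(4 * n_files, 20)))
  })[seq_len(n_files)]
  layout <- template_layout()
  files <- lapply(seq_len(n_files), function(i) {
    tpl <- withr::with_seed(seed + i, random_template(layout, address = addrs[i]))
    file_record(addrs[i], setNames(tpl, sprintf("%s_001", LETTERS[i])),
                copies = copies)
  })
  names(files) <- LETTERS[seq_len(n_files)]
  storage_database(files)
}
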