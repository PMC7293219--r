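## Overhang-address design: candidate generation, mutual Hamming-distance
## orthogonality, payload-conflict screening, and the Monte Carlo survey that
## contrasts PCR-style access (addresses must avoid the payload sequence
## space) with overhang-only access (they need not).

#' Generate candidate overhang addresses
#'
#' Uniform random 20-mers filtered to standard primer heuristics: GC fraction
#' within `gc_range` and homopolymer runs no longer than `max_homopolymer`.
#' Generation order is the greedy screening order, so a fixed seed fixes the
#' whole design.
#'
#' @param n Number of candidates to return.
#' @param address_length Address length in nt (default 20).
#' @param gc_range Allowed GC fraction (default `c(0.40, 0.60)`).
#' @param max_homopolymer Longest allowed single-base run (default 3).
#' @param seed RNG seed.
#' @return Character vector of `n` candidate addresses.
#' @export
generate_address_candidates <- function(n, address_length = 20L,
                                        gc_range = c(0.40, 0.60),
                                        max_homopolymer = 3L, seed = 1L) {
  stopifnot(n >= 0)
  out <- character(0)
  withr::with_seed(seed, {
    while (length(out) < n) {
      batch <- random_dna(max(2L * (n - length(out)), 64L), address_length)
      gc <- gc_fraction(batch)
      ok <- gc >= gc_range[1] & gc <= gc_range[2] &
        !grepl(sprintf("A{%1$d}|C{%1$d}|G{%1$d}|T{%1$d}", max_homopolymer + 1L),
               batch)
      out <- c(out, batch[ok])
    }
  })
  out[seq_len(n)]
}

#' Greedy mutual-orthogonality filter
#'
#' Accept-in-order screening: a candidate survives if its Hamming distance to
#' every previously accepted address AND to each accepted address's reverse
#' complement is at least `threshold`. The reverse complement is screened
#' because an access oligo can meet either strand of a melted duplex.
#'
#' @param candidates Character vector of equal-length candidates, in greedy
#'   order.
#' @param threshold Minimum pairwise Hamming distance (default 6).
#' @return Character vector of survivors (a subset of `candidates`, order
#'   preserved), with attribute `kept` (logical per candidate).
#' @export
mutual_orthogonality_filter <- function(candidates, threshold = 6L) {
  if (length(candidates) == 0L) return(candidates)
  validate_dna(candidates)
  stopifnot(length(unique(nchar(candidates))) == 1L)
  keep <- greedy_orthogonal_cpp(candidates, as.integer(threshold))
  out <- candidates[keep]
  attr(out, "kept") <- keep
  out
}

#' Does an address conflict with a payload sequence?
#'
#' TRUE iff the minimum Hamming distance between the address (or its reverse
#' complement) and any address-length sliding window over the strand (or its
#' reverse complement) is below `threshold`. This is the screen PCR-style
#' access must apply — a melted duplex exposes its payload to primers — and
#' overhang-only access can skip.
#'
#' @param address Address sequence (character scalar).
#' @param strand Strand sequence(s), each at least as long as the address.
#' @param threshold Conflict when distance `< threshold` (default 6).
#' @return Logical scalar.
#' @export
payload_conflict <- function(address, strand, threshold = 6L) {
  validate_dna(address)
  validate_dna(strand)
  if (any(nchar(strand) < nchar(address))) {
    stop("strand shorter than address")
  }
  min_payload_distance_cpp(address, strand) < threshold
}

#' Build a synthetic codeword database for the survey
#'
#' Encodes seeded random payload bytes at codeword length `L` into
#' `n_strands` full templates (payload codewords + promoter region +
#' a neutral address placeholder), the database the Monte Carlo survey
#' screens candidate addresses against.
#'
#' @param n_strands Number of strands.
#' @param L Codeword length.
#' @param codec Optional pre-built `codec_spec` (default
#'   `make_codeword_table(L)`).
#' @param seed RNG seed.
#' @return Character vector of template sequences.
#' @export
make_survey_database <- function(n_strands, L, codec = NULL, seed = 1L) {
  stopifnot(n_strands >= 0)
  if (is.null(codec)) codec <- make_codeword_table(L)
  data_cw <- codec$payload_capacity_nt %/% codec$L - codec$index_codewords
  n_bytes <- n_strands * data_cw
  payload <- withr::with_seed(seed, {
    as.raw(sample.int(256L, n_bytes, replace = TRUE) - 1L)
  })
  addr <- strrep("A", 20L) # placeholder; the survey screens payloads only
  as.character(encode(payload, codec, address = addr))
}

#' Monte Carlo survey of usable addresses (PCR vs DORIS access)
#'
#' Screens `n_candidates` seeded random candidates. Both access modes apply
#' the mutual orthogonality filter; PCR mode additionally rejects candidates
#' conflicting with the payload of any sampled database strand, while DORIS
#' (overhang-only) mode does not because the duplex payload never melts
#' during access. Payload conflicts are assessed against a random sample of
#' `payload_sample` database strands; exhaustive screening of realistic
#' databases is intractable, and a large sample bounds the survivor count
#' tightly from above.
#'
#' @param n_candidates Number of candidate addresses.
#' @param database Character vector of database strands (from
#'   [make_survey_database()] or [encode()]); may be empty in DORIS mode.
#' @param mode `"DORIS"` or `"PCR"`.
#' @param threshold Hamming-distance threshold (default 6).
#' @param seed RNG seed (candidate generation + strand sampling).
#' @param payload_sample Max database strands screened per survey
#'   (default 1e4); `Inf` for full enumeration.
#' @param L Codeword length the database was built at (recorded in the
#'   result; `NA` if unknown).
#' @param candidates Optional explicit candidate vector (overrides
#'   `n_candidates`/seeded generation so the same candidates can be surveyed
#'   across modes and databases).
#' @return An object of class `survey_result`: list with `mode`, `L`,
#'   `candidates_tested`, `survivors`, `survivor_addresses`,
#'   `capacity_bytes`, `threshold`, `seed`.
#' @export
monte_carlo_survey <- function(n_candidates, database,
                               mode = c("DORIS", "PCR"), threshold = 6L,
                               seed = 1L, payload_sample = 1e4, L = NA,
                               candidates = NULL) {
  mode <- match.arg(mode)
  if (mode == "PCR" && length(database) == 0L) {
    stop("PCR-mode survey requires a non-empty database")
  }
  if (is.null(candidates)) {
    candidates <- generate_address_candidates(n_candidates, seed = seed)
  }
  ortho <- mutual_orthogonality_filter(candidates, threshold)
  surv <- as.character(ortho)
  if (mode == "PCR" && length(surv) > 0L) {
    db <- database
    if (is.finite(payload_sample) && length(db) > payload_sample) {
      db <- withr::with_seed(seed + 1L, sample(db, payload_sample))
    }
    conflict <- payload_conflict_batch_cpp(surv, db, as.integer(threshold))
    surv <- surv[!conflict]
  }
  dens <- if (is.na(L)) NA_real_ else density(L)
  structure(
    list(mode = mode, L = L, candidates_tested = length(candidates),
         survivors = length(surv), survivor_addresses = surv,
         capacity_bytes = if (is.na(dens)) NA_real_ else
           capacity(length(surv), dens),
         threshold = as.integer(threshold), seed = seed),
    class = "survey_result"
  )
}

#' @export
print.survey_result <- function(x, ...) {
  cat(sprintf(
    "survey_result [%s]: L = %s, %d/%d candidates survive, capacity %.3g B\n",
    x$mode, as.character(x$L), x$survivors, x$candidates_tested,
    if (is.na(x$capacity_bytes)) NA else x$capacity_bytes
  ))
  invisible(x)
}

#' Capacity curve across codeword lengths
#'
#' Runs [monte_carlo_survey()] at each codeword length against a fresh
#' synthetic database of `n_strands` strands encoded at that length, joining
#' the survivor counts with the analytic density and capacity models. The
#' same candidate set (fixed by `seed`) is used at every L so the
#' overhang-mode counts are directly comparable.
#'
#' @param L_values Codeword lengths to evaluate (default `c(4, 6, 8, 10, 12)`).
#' @param mode `"DORIS"` or `"PCR"`.
#' @param n_candidates Candidates per survey.
#' @param n_strands Database strands per L.
#' @param threshold Hamming threshold (default 6).
#' @param seed RNG seed.
#' @param payload_sample Strands sampled for conflict screening (default 1e4).
#' @return A data frame with columns `mode`, `L`, `candidates`, `survivors`,
#'   `density`, `capacity`, `seed`.
#' @export
capacity_curve <- function(L_values = c(4L, 6L, 8L, 10L, 12L),
                           mode = c("DORIS", "PCR"), n_candidates = 1e4,
                           n_strands = 1e5, threshold = 6L, seed = 1L,
                           payload_sample = 1e4) {
  mode <- match.arg(mode)
  cands <- generate_address_candidates(n_candidates, seed = seed)
  rows <- lapply(L_values, function(L) {
    db <- make_survey_database(n_strands, L, seed = seed + L)
    res <- monte_carlo_survey(
      n_candidates, db, mode = mode, threshold = threshold, seed = seed,
      payload_sample = payload_sample, L = L, candidates = cands
    )
    data.frame(mode = mode, L = L, candidates = res$candidates_tested,
               survivors = res$survivors, density = density(L),
               capacity = res$capacity_bytes, seed = seed)
  })
  do.call(rbind, rows)
}
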