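## Stochastic simulator of the storage lifecycle: oligo-based file
## separation, on-bead in vitro transcription (IVT), return of the file to
## the database, repeated access, and the toehold-mediated file operations
## lock / unlock / rename / delete. All randomness is binomial/Poisson on
## integer copy counts, so a separation moves copies without duplicating
## them and copy counts are conserved exactly across a separate/return
## round trip (up to the modelled losses).

STRAND_STATES <- c("EXPOSED", "LOCKED", "RENAMED", "BLOCKED", "BEAD_BOUND")

strand_df <- function(id, template, copies, state, effective_address,
                      lock = NA_character_, lock_toehold = NA_integer_,
                      file = NA_character_) {
  n <- length(id)
  data.frame(id = id, template = rep_len(template, n),
             copies = rep_len(as.integer(copies), n),
             state = rep_len(state, n),
             effective_address = rep_len(effective_address, n),
             lock = rep_len(lock, n),
             lock_toehold = rep_len(as.integer(lock_toehold), n),
             file = rep_len(file, n), stringsAsFactors = FALSE)
}

## merge rows identical in everything but copies
collapse_rows <- function(df) {
  if (nrow(df) <= 1L) return(df)
  key <- do.call(paste, c(df[setdiff(names(df), "copies")], sep = "\r"))
  if (!anyDuplicated(key)) return(df)
  agg <- rowsum(df$copies, key)
  first <- df[!duplicated(key), , drop = FALSE]
  first$copies <- as.integer(agg[match(
    do.call(paste, c(first[setdiff(names(first), "copies")], sep = "\r")),
    rownames(agg)
  )])
  rownames(first) <- NULL
  first
}

#' Construct a file record
#'
#' A file is the multiset of ss-dsDNA strands sharing one exposed overhang
#' address, with integer copy counts.
#'
#' @param address The file's 20 nt overhang address.
#' @param templates Named character vector of member strand templates (names
#'   are strand ids).
#' @param copies Integer copy count per strand (recycled).
#' @return An object of class `file_record`.
#' @export
file_record <- function(address, templates, copies = 1L) {
  validate_dna(address)
  if (length(templates) > 0L) validate_dna(templates)
  ids <- names(templates)
  if (is.null(ids)) ids <- sprintf("s%04d", seq_along(templates))
  copies <- rep_len(as.integer(copies), length(templates))
  stopifnot(all(copies >= 0L))
  structure(
    list(address = address,
         strands = strand_df(ids, unname(templates), copies, "EXPOSED",
                             address)),
    class = "file_record"
  )
}

#' @export
print.file_record <- function(x, ...) {
  cat(sprintf("file_record: address %s, %d strand row(s), %d total copies\n",
              x$address, nrow(x$strands), sum(x$strands$copies)))
  invisible(x)
}

#' Construct a database of files
#'
#' @param files Named list of [file_record()]s (names are file labels, e.g.
#'   `A`, `B`, `C`).
#' @return An object of class `storage_database`.
#' @export
storage_database <- function(files) {
  stopifnot(is.list(files), length(names(files)) == length(files))
  addrs <- vapply(files, `[[`, character(1), "address")
  if (anyDuplicated(addrs)) stop("files must have distinct addresses")
  structure(list(files = files, log = list()), class = "storage_database")
}

#' @export
print.storage_database <- function(x, ...) {
  cat(sprintf("storage_database: %d file(s)\n", length(x$files)))
  for (nm in names(x$files)) {
    f <- x$files[[nm]]
    cat(sprintf("  %s @%s: %d copies\n", nm, f$address,
                sum(f$strands$copies)))
  }
  invisible(x)
}

#' Total copies per file
#' @param db A `storage_database`.
#' @return Named numeric vector of total copy counts.
#' @export
file_copy_counts <- function(db) {
  vapply(db$files, function(f) sum(f$strands$copies), numeric(1))
}

#' Access-cycle parameters
#'
#' Tunables of one full access cycle (separate -> IVT -> return) and of the
#' toehold operations. The per-cycle survival of captured copies is
#' calibrated so that a file accessed with probability
#' `separation_probability` retains `per_access_retention` of its copies per
#' cycle in expectation: uncaptured copies stay with probability 1, and
#' captured copies survive IVT + elution with probability
#' `s = 1 - (1 - per_access_retention) / separation_probability`. When
#' `ivt_loss_rate` is `NULL` it is derived from `s` (all loss charged to the
#' IVT/bead stage, with `elution_efficiency` left at its own default):
#' `(1 - ivt_loss_rate)^ivt_hours * elution_efficiency = s`.
#'
#' @param separation_probability Capture probability per copy for a perfectly
#'   matched exposed overhang (default 0.5).
#' @param per_access_retention Fraction of an accessed file surviving one
#'   full cycle (default 0.87, i.e. 0.5^(1/5): about half a file left after
#'   five accesses).
#' @param ivt_hours IVT duration in hours (default 8).
#' @param ivt_loss_rate Per-hour loss fraction of the bead-bound file;
#'   derived from the calibration when `NULL`.
#' @param elution_efficiency Fraction of surviving bound copies returned to
#'   the database (default 1).
#' @param transcripts_per_copy_hour Expected transcripts per template copy
#'   per hour of IVT (default 10).
#' @param temperature_celsius Operation temperature (default 25).
#' @param lock_melt_celsius Temperature above which a lock melts off and no
#'   longer blocks access (default 45).
#' @param lock_leak_fraction Fraction of copies left unlocked when the lock
#'   is added below `lock_melt_celsius` (default 0.05).
#' @return An object of class `access_params`.
#' @export
access_params <- function(separation_probability = 0.5,
                          per_access_retention = 0.87,
                          ivt_hours = 8, ivt_loss_rate = NULL,
                          elution_efficiency = 1,
                          transcripts_per_copy_hour = 10,
                          temperature_celsius = 25,
                          lock_melt_celsius = 45,
                          lock_leak_fraction = 0.05) {
  stopifnot(
    separation_probability >= 0, separation_probability <= 1,
    per_access_retention >= 0, per_access_retention <= 1,
    ivt_hours >= 0, elution_efficiency >= 0, elution_efficiency <= 1,
    lock_leak_fraction >= 0, lock_leak_fraction <= 1
  )
  if (is.null(ivt_loss_rate)) {
    if (!missing(elution_efficiency)) {
      # stage losses supplied manually: no retention-driven calibration
      ivt_loss_rate <- 0
    } else {
      s <- if (separation_probability > 0) {
        1 - (1 - per_access_retention) / separation_probability
      } else 1
      if (s < 0) stop("per_access_retention unreachable at this separation probability")
      per_stage <- s / elution_efficiency
      if (per_stage > 1) stop("elution efficiency too low for the calibration")
      ivt_loss_rate <- if (ivt_hours > 0) 1 - per_stage^(1 / ivt_hours) else 0
    }
  }
  stopifnot(ivt_loss_rate >= 0, ivt_loss_rate <= 1)
  structure(
    list(separation_probability = separation_probability,
         per_access_retention = per_access_retention,
         ivt_hours = ivt_hours, ivt_loss_rate = ivt_loss_rate,
         elution_efficiency = elution_efficiency,
         transcripts_per_copy_hour = transcripts_per_copy_hour,
         temperature_celsius = temperature_celsius,
         lock_melt_celsius = lock_melt_celsius,
         lock_leak_fraction = lock_leak_fraction),
    class = "access_params"
  )
}

## capture probability of one strand row for a given access oligo
capture_prob <- function(row, oligo, params, temperature_c) {
  target <- revcomp(oligo)
  p <- params$separation_probability
  if (row$state %in% c("EXPOSED", "RENAMED")) {
    if (row$effective_address == target) return(p)
  } else if (row$state == "LOCKED") {
    if (temperature_c > params$lock_melt_celsius &&
        row$effective_address == target) {
      return(p)
    }
  }
  0
}

#' Separate a file from the database with a biotinylated access oligo
#'
#' In overhang (`"DORIS"`) mode each copy whose exposed overhang is the exact
#' reverse complement of the oligo is captured with probability
#' `separation_probability` (binomial on copy counts); locked copies are
#' capturable only above `lock_melt_celsius`, blocked copies never. In
#' `"PCR"` mode the duplex melts every cycle, so state rules are void: the
#' oligo primes any strand whose address region matches, and additionally any
#' internal payload site, emitting truncated-product records carrying the
#' truncation coordinate.
#'
#' @param db A [storage_database()].
#' @param oligo Access oligo (reverse complement of the target address).
#' @param params An [access_params()].
#' @param mode `"DORIS"` or `"PCR"`.
#' @param temperature_celsius Access temperature; defaults to
#'   `params$temperature_celsius`.
#' @return List: `retained` (database of uncaptured copies), `bound`
#'   (`file_record` of captured copies, with a `file` column recording each
#'   strand's file of origin), `truncated` (data frame of truncated-product
#'   records; PCR mode only).
#' @export
separate <- function(db, oligo, params = access_params(),
                     mode = c("DORIS", "PCR"),
                     temperature_celsius = params$temperature_celsius) {
  stopifnot(inherits(db, "storage_database"))
  mode <- match.arg(mode)
  validate_dna(oligo)
  target <- revcomp(oligo)
  bound_rows <- list()
  trunc_rows <- list()
  retained <- db
  for (nm in names(db$files)) {
    f <- db$files[[nm]]
    if (nrow(f$strands) == 0L) next
    rows <- f$strands
    for (k in seq_len(nrow(rows))) {
      row <- rows[k, ]
      if (mode == "DORIS") {
        p <- capture_prob(row, oligo, params, temperature_celsius)
        hit_internal <- FALSE
      } else {
        n <- nchar(row$template)
        addr_region <- substr(row$template, n - nchar(target) + 1L, n)
        payload <- substr(row$template, 1L, n - nchar(target))
        site_f <- regexpr(target, payload, fixed = TRUE)
        site_r <- regexpr(oligo, payload, fixed = TRUE)
        hit_internal <- site_f > 0L || site_r > 0L
        p <- if (addr_region == target || hit_internal) {
          params$separation_probability
        } else 0
      }
      if (p > 0 && row$copies > 0L) {
        cap <- rbinom(1L, row$copies, p)
        if (cap > 0L) {
          b <- row
          b$copies <- cap
          b$file <- nm
          bound_rows[[length(bound_rows) + 1L]] <- b
          rows$copies[k] <- row$copies - cap
          if (mode == "PCR" && hit_internal) {
            coord <- max(site_f, site_r)
            trunc_rows[[length(trunc_rows) + 1L]] <- data.frame(
              file = nm, id = row$id, site = as.integer(coord),
              product_length = nchar(row$template) - as.integer(coord) + 1L,
              copies = cap, stringsAsFactors = FALSE
            )
          }
        }
      }
    }
    f$strands <- rows
    retained$files[[nm]] <- f
  }
  bound <- structure(
    list(address = target,
         strands = if (length(bound_rows)) {
           collapse_rows(do.call(rbind, bound_rows))
         } else strand_df(character(0), character(0), integer(0),
                          character(0), character(0))),
    class = "file_record"
  )
  truncated <- if (length(trunc_rows)) do.call(rbind, trunc_rows) else
    data.frame(file = character(0), id = character(0), site = integer(0),
               product_length = integer(0), copies = integer(0))
  retained$log <- c(retained$log, list(list(
    op = "separate", oligo = oligo, mode = mode,
    temperature_celsius = temperature_celsius,
    captured = sum(bound$strands$copies)
  )))
  list(retained = retained, bound = bound, truncated = truncated)
}

#' In vitro transcription of a bead-bound file
#'
#' Transcript counts per strand are Poisson with mean
#' `copies * ivt_hours * transcripts_per_copy_hour`; the bound copies decay
#' binomially with survival `(1 - ivt_loss_rate)^ivt_hours` (bead unbinding
#' and degradation lumped into one rate). Transcript sequences are the
#' payload region downstream of the promoter.
#'
#' @param bound_file `file_record` from [separate()].
#' @param params An [access_params()].
#' @param address_length,promoter_region_length Template geometry used to
#'   slice out the transcribed payload (defaults 20 and 23).
#' @return List: `transcripts` (data frame `id`, `sequence`, `count`),
#'   `surviving_file` (the bound file after decay).
#' @export
ivt <- function(bound_file, params = access_params(), address_length = 20L,
                promoter_region_length = 23L) {
  stopifnot(inherits(bound_file, "file_record"))
  rows <- bound_file$strands
  hours <- params$ivt_hours
  if (nrow(rows) == 0L || hours == 0) {
    return(list(
      transcripts = data.frame(id = character(0), sequence = character(0),
                               count = integer(0)),
      surviving_file = bound_file
    ))
  }
  counts <- rpois(nrow(rows),
                  rows$copies * hours * params$transcripts_per_copy_hour)
  payload_end <- nchar(rows$template) - address_length -
    promoter_region_length
  transcripts <- data.frame(
    id = rows$id,
    sequence = substr(rows$template, 1L, pmax(payload_end, 0L)),
    count = counts, stringsAsFactors = FALSE
  )
  survival <- (1 - params$ivt_loss_rate)^hours
  rows$copies <- rbinom(nrow(rows), rows$copies, survival)
  bound_file$strands <- rows
  list(transcripts = transcripts, surviving_file = bound_file)
}

#' Return a separated file to the database
#'
#' Each surviving bound copy is eluted back into its file of origin with
#' probability `elution_efficiency` (binomial).
#'
#' @param db The retained database.
#' @param file `file_record` of bound strands (with `file` origin column).
#' @param params An [access_params()].
#' @return The database with eluted copies re-added.
#' @export
return_file <- function(db, file, params = access_params()) {
  stopifnot(inherits(db, "storage_database"), inherits(file, "file_record"))
  rows <- file$strands
  if (nrow(rows) == 0L) return(db)
  rows$copies <- rbinom(nrow(rows), rows$copies, params$elution_efficiency)
  for (nm in unique(rows$file)) {
    back <- rows[rows$file == nm & rows$copies > 0L, , drop = FALSE]
    if (nrow(back) == 0L) next
    if (!nm %in% names(db$files)) stop(sprintf("unknown file of origin '%s'", nm))
    back$file <- NA_character_
    db$files[[nm]]$strands <- collapse_rows(
      rbind(db$files[[nm]]$strands, back)
    )
  }
  db$log <- c(db$log, list(list(op = "return_file",
                                returned = sum(rows$copies))))
  db
}

#' Repeatedly access one file and track retention
#'
#' Applies separate -> IVT -> return `n` times for the file at `address` and
#' reports each file's retention (current copies / starting copies, as a
#' percentage) after every cycle. Non-accessed files are untouched and retain
#' 100%.
#'
#' @param db A [storage_database()].
#' @param address Address of the file to access.
#' @param n Number of access cycles.
#' @param params An [access_params()].
#' @param seed Optional RNG seed for the whole trajectory.
#' @return List: `db` (final database), `trajectory` (data frame `cycle`,
#'   `file`, `retention_pct`, including cycle 0 = initial state).
#' @export
repeat_access <- function(db, address, n, params = access_params(),
                          seed = NULL) {
  stopifnot(inherits(db, "storage_database"), n >= 0)
  run <- function() {
    initial <- file_copy_counts(db)
    oligo <- revcomp(address)
    traj <- data.frame(cycle = 0L, file = names(initial),
                       retention_pct = 100, stringsAsFactors = FALSE)
    for (cyc in seq_len(n)) {
      sep <- separate(db, oligo, params, mode = "DORIS")
      post_ivt <- ivt(sep$bound, params)
      db <- return_file(sep$retained, post_ivt$surviving_file, params)
      now <- file_copy_counts(db)
      traj <- rbind(traj, data.frame(
        cycle = cyc, file = names(initial),
        retention_pct = 100 * now[names(initial)] /
          pmax(initial, 1e-300),
        stringsAsFactors = FALSE
      ))
    }
    rownames(traj) <- NULL
    list(db = db, trajectory = traj)
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Minimum initial copies per distinct sequence for a number of accesses
#'
#' Design rule for sizing a database: if a fraction `s` of an accessed file
#' survives `n_accesses` full cycles, at least `ceiling(1/s)` copies of each
#' distinct sequence are needed initially to expect one surviving copy. The
#' survival is taken to the two significant figures at which it is known
#' empirically (about 50% after five accesses at the default calibration),
#' giving the familiar budget of 2 copies per 5 accesses.
#'
#' @param n_accesses Number of access cycles (default 5).
#' @param params An [access_params()].
#' @param digits Significant rounding applied to the compounded survival
#'   (default 2, matching the precision of the measured retention).
#' @return Integer copy count.
#' @examples
#' min_initial_copies(5) # 2
#' @export
min_initial_copies <- function(n_accesses = 5L, params = access_params(),
                               digits = 2L) {
  stopifnot(n_accesses >= 1)
  s <- round(params$per_access_retention^n_accesses, digits)
  if (s <= 0) stop("no copies survive this many accesses")
  as.integer(ceiling(1 / s))
}

#' Metrics of one access: specificity, efficiency, retention, abundance
#'
#' File specificity (% of the separated sample that belongs to each file),
#' separation efficiency (% of each file's pre-separation copies present in
#' the eluted sample), retention rate (% of each file's starting copies still
#' present afterwards), and normalized per-strand abundance (post / pre copy
#' ratio). Metrics with zero denominators are reported as `NA` (undefined),
#' never 0.
#'
#' @param before Database before the operation.
#' @param sample `file_record` of the separated/eluted sample (with `file`
#'   origin column, as produced by [separate()]).
#' @param after Database after the operation.
#' @return An object of class `metrics_report`: list of
#'   `file_specificity_pct`, `separation_efficiency_pct`,
#'   `retention_rate_pct` (named by file) and `normalized_abundance` (named
#'   by strand id).
#' @export
compute_metrics <- function(before, sample, after) {
  stopifnot(inherits(before, "storage_database"),
            inherits(after, "storage_database"),
            inherits(sample, "file_record"))
  pre <- file_copy_counts(before)
  post <- file_copy_counts(after)
  in_sample <- setNames(numeric(length(pre)), names(pre))
  if (nrow(sample$strands) > 0L) {
    agg <- rowsum(sample$strands$copies, sample$strands$file)
    in_sample[rownames(agg)] <- agg[, 1L]
  }
  total_sample <- sum(in_sample)
  spec <- if (total_sample > 0) 100 * in_sample / total_sample else
    setNames(rep(NA_real_, length(pre)), names(pre))
  eff <- ifelse(pre > 0, 100 * in_sample / pre, NA_real_)
  ret <- ifelse(pre > 0, 100 * post / pre, NA_real_)
  pre_ids <- do.call(rbind, lapply(names(before$files), function(nm) {
    s <- before$files[[nm]]$strands
    if (nrow(s) == 0L) return(NULL)
    data.frame(id = s$id, copies = s$copies, stringsAsFactors = FALSE)
  }))
  post_ids <- do.call(rbind, lapply(names(after$files), function(nm) {
    s <- after$files[[nm]]$strands
    if (nrow(s) == 0L) return(NULL)
    data.frame(id = s$id, copies = s$copies, stringsAsFactors = FALSE)
  }))
  norm_ab <- NULL
  if (!is.null(pre_ids)) {
    pre_by <- rowsum(pre_ids$copies, pre_ids$id)
    post_by <- if (!is.null(post_ids)) rowsum(post_ids$copies, post_ids$id)
      else NULL
    norm_ab <- setNames(rep(NA_real_, nrow(pre_by)), rownames(pre_by))
    for (id in rownames(pre_by)) {
      denom <- pre_by[id, 1L]
      num <- if (!is.null(post_by) && id %in% rownames(post_by))
        post_by[id, 1L] else 0
      norm_ab[id] <- if (denom > 0) num / denom else NA_real_
    }
  }
  structure(
    list(file_specificity_pct = spec,
         separation_efficiency_pct = setNames(eff, names(pre)),
         retention_rate_pct = setNames(ret, names(pre)),
         normalized_abundance = norm_ab),
    class = "metrics_report"
  )
}

#' @export
print.metrics_report <- function(x, ...) {
  cat("metrics_report\n  specificity (%):",
      paste(sprintf("%s=%.1f", names(x$file_specificity_pct),
                    x$file_specificity_pct), collapse = " "),
      "\n  separation efficiency (%):",
      paste(sprintf("%s=%.1f", names(x$separation_efficiency_pct),
                    x$separation_efficiency_pct), collapse = " "),
      "\n  retention (%):",
      paste(sprintf("%s=%.1f", names(x$retention_rate_pct),
                    x$retention_rate_pct), collapse = " "), "\n")
  invisible(x)
}
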