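## Run configuration, seed substreams, database serialisation, and fixture
## generation shared by every module and by the command-line interface.

default_config <- function() {
  list(
    seed = 1L,
    codec = list(L = 4L, index_codewords = 5L, payload_capacity_nt = 160L,
                 method = "lexicographic", max_homopolymer = Inf),
    address_design = list(threshold = 6L, n_candidates = 10000L,
                          address_length = 20L, gc_min = 0.40, gc_max = 0.60,
                          max_homopolymer = 3L, payload_sample = 10000L),
    access = list(separation_probability = 0.5, per_access_retention = 0.87,
                  ivt_hours = 8, elution_efficiency = 1,
                  transcripts_per_copy_hour = 10, temperature_celsius = 25,
                  lock_melt_celsius = 45, lock_leak_fraction = 0.05),
    pool = list(barcode_length = 10L, n_reads = 10000L,
                sub_rate = 0, ins_rate = 0, del_rate = 0),
    output_dir = "."
  )
}

check_config <- function(cfg) {
  with(cfg, {
    stopifnot(seed >= 0)
    stopifnot(codec$L >= 4, codec$L <= 12)
    if (cfg$address_design$threshold < 0) {
      stop("config: address_design$threshold must be >= 0")
    }
    stopifnot(address_design$n_candidates >= 0,
              address_design$gc_min <= address_design$gc_max)
    stopifnot(access$separation_probability >= 0,
              access$separation_probability <= 1,
              access$per_access_retention >= 0,
              access$per_access_retention <= 1)
    stopifnot(pool$n_reads >= 0, pool$sub_rate >= 0, pool$ins_rate >= 0,
              pool$del_rate >= 0)
  })
  invisible(cfg)
}

#' Load a run configuration from YAML
#'
#' Missing keys are filled with the documented defaults; unknown keys are
#' rejected with a message naming them; values are validated (thresholds and
#' rates non-negative, probabilities in `[0, 1]`). An empty file yields the
#' full default configuration.
#'
#' @param path Path to a YAML config file, or `NULL` for pure defaults.
#' @return A validated config list of class `run_config`.
#' @export
load_config <- function(path = NULL) {
  cfg <- default_config()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    user <- yaml::read_yaml(path)
    if (is.null(user)) user <- list()
    bad <- setdiff(names(user), names(cfg))
    if (length(bad)) stop("unknown config key(s): ", paste(bad, collapse = ", "))
    for (k in names(user)) {
      if (is.list(cfg[[k]]) && is.list(user[[k]])) {
        badk <- setdiff(names(user[[k]]), names(cfg[[k]]))
        if (length(badk)) {
          stop(sprintf("unknown config key(s) under '%s': %s", k,
                       paste(badk, collapse = ", ")))
        }
        cfg[[k]] <- modifyList(cfg[[k]], user[[k]])
      } else {
        cfg[[k]] <- user[[k]]
      }
    }
  }
  check_config(cfg)
  structure(cfg, class = "run_config")
}

#' Save a configuration to YAML
#' @param cfg A `run_config`.
#' @param path Output path.
#' @return Invisibly `path`.
#' @export
save_config <- function(cfg, path) {
  cfg <- unclass(cfg)
  cfg$codec$max_homopolymer <-
    if (is.finite(cfg$codec$max_homopolymer)) cfg$codec$max_homopolymer else
      .Machine$integer.max
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' Deterministic sub-seed for a labelled operation
#'
#' Every stochastic stage draws its seed from the global seed plus a stable
#' operation label, so multi-stage pipelines replay exactly.
#'
#' @param seed Global integer seed.
#' @param label Stable operation label (e.g. `"survey"`, `"reads"`).
#' @return An integer seed in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_len(nchar(label)))
  as.integer((as.numeric(seed) * 7919 + h) %% (2^31 - 1))
}

#' Serialise a database to tagged FASTA
#'
#' One record per strand row; copy counts, states, file labels and effective
#' addresses live in `key=value` header tags.
#'
#' @param db A [storage_database()].
#' @param path Output FASTA path.
#' @return Invisibly `path`.
#' @export
write_database_fasta <- function(db, path) {
  stopifnot(inherits(db, "storage_database"))
  rows <- do.call(rbind, lapply(names(db$files), function(nm) {
    s <- db$files[[nm]]$strands
    if (nrow(s) == 0L) return(NULL)
    s$file <- nm
    s$address <- db$files[[nm]]$address
    s
  }))
  if (is.null(rows)) stop("empty database")
  seqs <- setNames(rows$template, rows$id)
  write_strand_fasta(seqs, path, tags = data.frame(
    file = rows$file, copies = rows$copies, state = rows$state,
    address = rows$address, effective_address = rows$effective_address,
    stringsAsFactors = FALSE
  ))
}

#' Read a database from tagged FASTA
#' @param path FASTA written by [write_database_fasta()].
#' @return A [storage_database()].
#' @export
read_database_fasta <- function(path) {
  tab <- read_strand_fasta(path)
  need <- c("file", "copies", "state", "address", "effective_address")
  if (!all(need %in% names(tab))) {
    stop("FASTA lacks database header tags: ",
         paste(setdiff(need, names(tab)), collapse = ", "))
  }
  files <- lapply(split(tab, tab$file), function(g) {
    structure(
      list(address = g$address[1L],
           strands = strand_df(g$id, g$sequence, as.integer(g$copies),
                               g$state, g$effective_address)),
      class = "file_record"
    )
  })
  storage_database(files)
}

#' Generate a small seeded fixture database
#'
#' Designs `n_files` mutually orthogonal addresses, encodes a seeded random
#' payload per file, and assembles a database with uniform copy counts — the
#' in-silico analogue of a small multi-file pool (e.g. a three-file A/B/C
#' database).
#'
#' @param n_files Number of files (default 3).
#' @param strands_per_file Distinct strands per file (default 4).
#' @param L Codeword length (default 4).
#' @param copies Copies per strand (default 100).
#' @param seed RNG seed.
#' @param fasta Optional path; when given the database is also written to
#'   tagged FASTA.
#' @return List: `db` (a [storage_database()]), `payloads` (list of raw
#'   vectors per file), `manifests` (encode manifests per file), `codec`,
#'   `addresses`.
#' @export
make_fixture_database <- function(n_files = 3L, strands_per_file = 4L,
                                  L = 4L, copies = 100L, seed = 1L,
                                  fasta = NULL) {
  stopifnot(n_files >= 1, strands_per_file >= 1)
  codec <- make_codeword_table(L)
  data_cw <- codec$payload_capacity_nt %/% L - codec$index_codewords
  cands <- generate_address_candidates(4L * n_files + 16L,
                                       seed = derive_seed(seed, "addresses"))
  addrs <- as.character(mutual_orthogonality_filter(cands))
  if (length(addrs) < n_files) stop("address design failed for fixture")
  addrs <- addrs[seq_len(n_files)]
  nm <- LETTERS[seq_len(n_files)]
  payloads <- list()
  manifests <- list()
  files <- list()
  for (i in seq_len(n_files)) {
    payload <- withr::with_seed(derive_seed(seed, paste0("payload", i)), {
      as.raw(sample.int(256L, strands_per_file * data_cw,
                        replace = TRUE) - 1L)
    })
    enc <- encode(payload, codec, address = addrs[i])
    payloads[[nm[i]]] <- payload
    manifests[[nm[i]]] <- attr(enc, "manifest")
    tpl <- setNames(as.character(enc),
                    sprintf("%s_%03d", nm[i], seq_along(enc)))
    files[[nm[i]]] <- file_record(addrs[i], tpl, copies = copies)
  }
  db <- storage_database(files)
  if (!is.null(fasta)) write_database_fasta(db, fasta)
  list(db = db, payloads = payloads, manifests = manifests, codec = codec,
       addresses = setNames(addrs, nm))
}

#' Run an ordered operation script against a database
#'
#' Executes a list of steps (as parsed from an operations YAML) in order.
#' Supported ops: `separate`, `ivt`, `return`, `lock`, `unlock`, `rename`,
#' `delete`, `metrics`. `separate` stores its bound file as the current
#' sample; `ivt` and `return` act on it; lock/unlock/rename/delete address a
#' file by label via the `file` field; `metrics` compares the current state
#' against the state at the last `snapshot` (implicitly the initial state).
#'
#' @param db A [storage_database()].
#' @param script List of steps; each a list with an `op` field plus
#'   op-specific fields (`oligo`, `file`, `lock`, `key`, `rename_oligo`,
#'   `block_oligo`, `temperature_celsius`, `mode`).
#' @param params An [access_params()].
#' @param seed RNG seed for the whole script.
#' @return List: `db` (final state), `report` (per-step results),
#'   `sample` (current bound file, if any).
#' @export
run_ops_script <- function(db, script, params = access_params(), seed = 1L) {
  stopifnot(inherits(db, "storage_database"))
  run <- function() {
    before <- db
    bound <- NULL
    report <- list()
    for (k in seq_along(script)) {
      step <- script[[k]]
      op <- step$op
      res <- switch(op,
        separate = {
          out <- separate(db, step$oligo, params,
                          mode = step$mode %||% "DORIS",
                          temperature_celsius = step$temperature_celsius %||%
                            params$temperature_celsius)
          db <- out$retained
          bound <- out$bound
          list(captured = sum(out$bound$strands$copies),
               truncated = nrow(out$truncated))
        },
        ivt = {
          if (is.null(bound)) stop("ivt before any separate")
          out <- ivt(bound, params)
          bound <- out$surviving_file
          list(transcripts = sum(out$transcripts$count))
        },
        `return` = {
          if (is.null(bound)) stop("return before any separate")
          db <- return_file(db, bound, params)
          bound <- NULL
          list(done = TRUE)
        },
        lock = {
          db$files[[step$file]] <- lock_file(
            db$files[[step$file]], step$lock,
            add_temperature_celsius = step$temperature_celsius %||% 98,
            params = params)
          list(done = TRUE)
        },
        unlock = {
          db$files[[step$file]] <- unlock_file(
            db$files[[step$file]], step$key,
            temperature_celsius = step$temperature_celsius %||% 25)
          list(done = TRUE)
        },
        rename = {
          db$files[[step$file]] <- rename_file(db$files[[step$file]],
                                                step$rename_oligo)
          list(done = TRUE)
        },
        delete = {
          db$files[[step$file]] <- delete_file(db$files[[step$file]],
                                                step$block_oligo)
          list(done = TRUE)
        },
        snapshot = {
          before <- db
          list(done = TRUE)
        },
        metrics = {
          sample <- bound
          if (is.null(sample)) {
            sample <- structure(list(
              address = "", strands = strand_df(character(0), character(0),
                                                integer(0), character(0),
                                                character(0))
            ), class = "file_record")
          }
          compute_metrics(before, sample, db)
        },
        stop("unknown op: ", op)
      )
      report[[k]] <- list(op = op, result = res)
    }
    list(db = db, report = report, sample = bound)
  }
  withr::with_seed(derive_seed(seed, "ops"), run())
}
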