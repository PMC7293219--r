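## Toehold-mediated in-storage file operations. A 50 nt lock anneals 20 nt of
## itself over the exposed overhang, leaving a 30 nt single-stranded toehold;
## the 50 nt key (full complement of the lock) invades at that toehold and
## unzips the lock at room temperature. A 40 nt rename oligo covers the old
## address and presents a new one; a 20 nt block oligo deletes the file by
## burying its overhang.

#' Default molar ratios of the file operations
#'
#' Reagent excesses used in the operations: file : lock : key : access oligo
#' = 1 : 10 : 10 : 15 for locking/unlocking, and file : renaming oligo :
#' access oligo = 1 : 10 : 15 for renaming. The simulator's oligo additions
#' assume these excesses (reactions run to completion up to the modelled
#' leak), and the ratios are recorded here so configurations can restate or
#' override them.
#'
#' @return Named list of ratio vectors.
#' @export
molar_ratios <- function() {
  list(
    lock_unlock = c(file = 1, lock = 10, key = 10, access_oligo = 15),
    rename = c(file = 1, rename_oligo = 10, access_oligo = 15)
  )
}

#' Construct a lock strand for an address
#'
#' `[30 nt toehold][20 nt complement of the address]`, 5'->3': the 3' half
#' anneals over the overhang, the 5' half dangles as the toehold the key
#' invades at.
#'
#' @param address The file address to lock.
#' @param toehold Optional explicit 30 nt toehold sequence; random when
#'   `NULL`.
#' @param seed RNG seed for the random toehold.
#' @return Character scalar, 50 nt lock strand.
#' @export
make_lock <- function(address, toehold = NULL, seed = 1L) {
  validate_dna(address)
  if (is.null(toehold)) {
    toehold <- withr::with_seed(seed, random_dna(1L, 30L))
  }
  stopifnot(nchar(toehold) == 30L)
  paste0(toehold, revcomp(address))
}

#' Key for a lock
#' @param lock_strand A 50 nt lock.
#' @return Its full reverse complement (the key).
#' @export
make_key <- function(lock_strand) revcomp(lock_strand)

#' Construct a rename oligo
#'
#' `[20 nt new address][20 nt complement of the old address]`, 5'->3': the 3'
#' half anneals over the old overhang and the 5' half is presented as the new
#' single-stranded address.
#'
#' @param old_address,new_address 20 nt addresses.
#' @return Character scalar, 40 nt rename oligo.
#' @export
make_rename_oligo <- function(old_address, new_address) {
  validate_dna(c(old_address, new_address))
  paste0(new_address, revcomp(old_address))
}

#' Lock a file
#'
#' Exposed copies transition to `LOCKED`, recording the lock and its 30 nt
#' toehold. Locking fidelity depends on the temperature the lock is added at:
#' at or above `lock_melt_celsius` (default 45) locking is complete; below it
#' a `lock_leak_fraction` of copies escapes locking and stays exposed
#' (binomial per strand).
#'
#' @param file A [file_record()].
#' @param lock_strand 50 nt lock containing the 20 nt complement of the
#'   file's address.
#' @param add_temperature_celsius Temperature the lock is annealed at
#'   (default 98).
#' @param params An [access_params()] (leak fraction, melt threshold).
#' @return The locked `file_record`.
#' @export
lock_file <- function(file, lock_strand,
                      add_temperature_celsius = 98,
                      params = access_params()) {
  stopifnot(inherits(file, "file_record"))
  validate_dna(lock_strand)
  if (nchar(lock_strand) != 50L) stop("lock must be 50 nt")
  comp <- revcomp(file$address)
  if (!grepl(comp, lock_strand, fixed = TRUE)) {
    stop("lock lacks the 20 nt complement of the file address")
  }
  toehold_len <- nchar(lock_strand) - nchar(comp)
  rows <- file$strands
  if (nrow(rows) == 0L) return(file)
  out <- list()
  for (k in seq_len(nrow(rows))) {
    row <- rows[k, ]
    if (row$state != "EXPOSED" || row$copies == 0L) {
      out[[length(out) + 1L]] <- row
      next
    }
    leak <- if (add_temperature_celsius >= params$lock_melt_celsius) 0L else
      rbinom(1L, row$copies, params$lock_leak_fraction)
    locked <- row$copies - leak
    if (locked > 0L) {
      lrow <- row
      lrow$copies <- locked
      lrow$state <- "LOCKED"
      lrow$lock <- lock_strand
      lrow$lock_toehold <- as.integer(toehold_len)
      out[[length(out) + 1L]] <- lrow
    }
    if (leak > 0L) {
      row$copies <- leak
      out[[length(out) + 1L]] <- row
    }
  }
  file$strands <- collapse_rows(do.call(rbind, out))
  file
}

#' Unlock a file with a key
#'
#' Toehold-mediated displacement works at any temperature from room
#' temperature up: if the key is the exact reverse complement of the lock,
#' every locked copy returns to `EXPOSED`. A mismatched key changes nothing
#' (with a warning).
#'
#' @param file A locked `file_record`.
#' @param key 50 nt key strand.
#' @param temperature_celsius Temperature the key is added at (default 25;
#'   displacement succeeds at 25 and above).
#' @return The unlocked `file_record`.
#' @export
unlock_file <- function(file, key, temperature_celsius = 25) {
  stopifnot(inherits(file, "file_record"))
  validate_dna(key)
  rows <- file$strands
  locked <- rows$state == "LOCKED"
  if (!any(locked)) return(file)
  matches <- !is.na(rows$lock) & rows$lock == revcomp(key)
  if (!any(locked & matches)) {
    warning("key does not match the lock; file stays locked")
    return(file)
  }
  hit <- locked & matches
  rows$state[hit] <- "EXPOSED"
  rows$lock[hit] <- NA_character_
  rows$lock_toehold[hit] <- NA_integer_
  file$strands <- collapse_rows(rows)
  file
}

#' Rename a file
#'
#' The 40 nt rename oligo anneals its 3' half over the old address and
#' presents its 5' half as the new address. All copies must have an exposed
#' overhang (locked or blocked strands have no toehold for the oligo).
#'
#' @param file A `file_record` with exposed strands.
#' @param rename_oligo 40 nt oligo from [make_rename_oligo()].
#' @return The renamed `file_record` (its `address` and every strand's
#'   `effective_address` become the new address; state `RENAMED`).
#' @export
rename_file <- function(file, rename_oligo) {
  stopifnot(inherits(file, "file_record"))
  validate_dna(rename_oligo)
  if (nchar(rename_oligo) != 40L) stop("rename oligo must be 40 nt")
  rows <- file$strands
  active <- rows$copies > 0L
  if (any(rows$state[active] %in% c("LOCKED", "BLOCKED"))) {
    stop("no exposed toehold: file has locked or blocked strands")
  }
  current <- unique(rows$effective_address[active])
  if (length(current) > 1L) stop("file strands present multiple addresses")
  if (length(current) == 1L &&
      substr(rename_oligo, 21L, 40L) != revcomp(current)) {
    stop("rename oligo lacks the complement of the current address")
  }
  new_address <- substr(rename_oligo, 1L, 20L)
  rows$effective_address[active] <- new_address
  rows$state[active] <- "RENAMED"
  file$strands <- collapse_rows(rows)
  file$address <- new_address
  file
}

#' Delete a file by blocking its overhang
#'
#' A 20 nt oligo fully complementary to the current address buries the
#' overhang; blocked copies answer to no access oligo thereafter.
#'
#' @param file A `file_record`.
#' @param block_oligo 20 nt oligo, exact reverse complement of the file's
#'   current address.
#' @return The blocked `file_record`.
#' @export
delete_file <- function(file, block_oligo) {
  stopifnot(inherits(file, "file_record"))
  validate_dna(block_oligo)
  rows <- file$strands
  if (nrow(rows) == 0L) return(file)
  if (nchar(block_oligo) != nchar(file$address)) {
    stop("block oligo must match the address length")
  }
  if (block_oligo != revcomp(file$address)) {
    stop("block oligo is not the complement of the file address")
  }
  target <- rows$state %in% c("EXPOSED", "RENAMED")
  rows$state[target] <- "BLOCKED"
  file$strands <- collapse_rows(rows)
  file
}
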