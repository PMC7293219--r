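## Data model for ss-dsDNA strands: a template ssDNA filled in by a single
## common primer, leaving the 3'-terminal address single stranded. Coordinates
## are 0-based, half-open, counted from the template 5' end.

#' Template layout for ss-dsDNA strands
#'
#' Describes how a template partitions, 5'->3', into a data payload region, a
#' fixed promoter region (carrying the T7 promoter / common primer site), and
#' a 3'-terminal address region that remains single stranded after fill-in.
#'
#' @param total_length Template length in nt (default 160).
#' @param address_length Address (overhang) length in nt at the 3' terminus
#'   (default 20).
#' @param promoter_region_length Length of the promoter region immediately 5'
#'   of the address (default 23).
#' @return An object of class `template_layout` with the three lengths and the
#'   derived half-open intervals `payload`, `promoter`, `address`.
#' @examples
#' template_layout()            # 117 nt payload + 23 nt promoter + 20 nt address
#' template_layout(203)         # payload sized for a 160 nt codeword region
#' @export
template_layout <- function(total_length = 160L, address_length = 20L,
                            promoter_region_length = 23L) {
  total_length <- as.integer(total_length)
  address_length <- as.integer(address_length)
  promoter_region_length <- as.integer(promoter_region_length)
  payload_length <- total_length - address_length - promoter_region_length
  if (payload_length < 0L) {
    stop("address + promoter region exceed total template length")
  }
  structure(
    list(
      total_length = total_length,
      address_length = address_length,
      promoter_region_length = promoter_region_length,
      payload = c(0L, payload_length),
      promoter = c(payload_length, payload_length + promoter_region_length),
      address = c(total_length - address_length, total_length)
    ),
    class = "template_layout"
  )
}

#' @export
print.template_layout <- function(x, ...) {
  cat(sprintf(
    "template_layout: %d nt = payload [%d,%d) + promoter [%d,%d) + address [%d,%d)\n",
    x$total_length, x$payload[1], x$payload[2],
    x$promoter[1], x$promoter[2], x$address[1], x$address[2]
  ))
  invisible(x)
}

#' Default promoter-region sequence
#'
#' The 23 nt region of the template immediately 5' of the address. It carries
#' the antisense of the common primer, so the primer anneals exactly once
#' inside it; the two leading `GG` bases pad the 21 nt primer site to the 23 nt
#' region length. The primer's own sequence contains the T7 promoter core, so
#' the filled-in duplex presents a functional promoter next to the overhang.
#'
#' @param primer The common fill-in primer (default [doris_primer()]).
#' @return Character scalar of length 23.
#' @export
default_promoter_region <- function(primer = doris_primer()) {
  paste0("GG", revcomp(primer))
}

#' Construct a random template obeying a layout
#'
#' Random payload and address with the fixed promoter region in between.
#' Intended for fixtures and simulations; real designs come from the codec.
#'
#' @param layout A [template_layout()].
#' @param address Address sequence (character, `address_length` nt); random if
#'   `NULL`.
#' @param promoter_region Promoter-region sequence; default
#'   [default_promoter_region()].
#' @return Character scalar template of `layout$total_length` nt.
#' @export
random_template <- function(layout = template_layout(), address = NULL,
                            promoter_region = default_promoter_region()) {
  stopifnot(inherits(layout, "template_layout"))
  if (nchar(promoter_region) != layout$promoter_region_length) {
    stop("promoter region length does not match layout")
  }
  if (is.null(address)) {
    address <- if (layout$address_length > 0L) {
      random_dna(1L, layout$address_length)
    } else ""
  }
  if (nchar(address) != layout$address_length) {
    stop("address length does not match layout")
  }
  payload_len <- layout$payload[2] - layout$payload[1]
  payload <- if (payload_len > 0L) random_dna(1L, payload_len) else ""
  paste0(payload, promoter_region, address)
}

#' Fill in a template to an ss-dsDNA strand (single-primer extension)
#'
#' Models one-pot conversion of an ssDNA template into a double-stranded
#' strand with a single-stranded 3' overhang: the common primer anneals at its
#' unique site inside the promoter region and polymerase fill-in produces a
#' blunt duplex covering everything 5' of the address, leaving the 3'-terminal
#' `address_length` bases exposed as the file address.
#'
#' Primer-site matching is exact: the reverse complement of `primer` must
#' occur exactly once in the template, inside the promoter region.
#'
#' @param template Character scalar, the ssDNA template (5'->3').
#' @param primer The fill-in primer; default [doris_primer()].
#' @param layout A [template_layout()] matching `nchar(template)`.
#' @return An object of class `ssdsdna_strand`: list with `template`,
#'   `duplex_interval` (0-based half-open), `state` (`"EXPOSED"`),
#'   `attachments` (empty list), `layout`.
#' @examples
#' tpl <- random_template()
#' s <- build_ssdsdna(tpl)
#' nchar(overhang_of(s)) # 20
#' @export
build_ssdsdna <- function(template, primer = doris_primer(),
                          layout = template_layout()) {
  validate_dna(template)
  stopifnot(inherits(layout, "template_layout"))
  if (nchar(template) != layout$total_length) {
    stop("template length does not match layout")
  }
  site <- revcomp(primer)
  hits <- gregexpr(site, template, fixed = TRUE)[[1L]]
  hits <- hits[hits > 0L]
  if (length(hits) == 0L) stop("no primer site in template")
  if (length(hits) > 1L) stop("ambiguous primer site: multiple matches")
  start0 <- hits[1L] - 1L
  end0 <- start0 + nchar(site)
  if (start0 < layout$promoter[1] || end0 > layout$promoter[2]) {
    stop("primer site lies outside the promoter region")
  }
  structure(
    list(
      template = template,
      duplex_interval = c(0L, layout$address[1]),
      state = "EXPOSED",
      attachments = list(),
      layout = layout
    ),
    class = "ssdsdna_strand"
  )
}

#' @export
print.ssdsdna_strand <- function(x, ...) {
  cat(sprintf(
    "ss-dsDNA strand: %d nt template, duplex [%d,%d), state %s, %d attachment(s)\n",
    nchar(x$template), x$duplex_interval[1], x$duplex_interval[2],
    x$state, length(x$attachments)
  ))
  invisible(x)
}

#' Exposed single-stranded overhang of a strand
#'
#' Returns the exposed 3'-terminal single-stranded region after masking any
#' positions covered by attachments (lock, rename, or block oligos). A fully
#' blocked or locked strand has an empty exposed overhang; for a locked strand
#' the lock's own single-stranded toehold is reported in the `"toehold"`
#' attribute (its length is what makes key-driven strand displacement work).
#'
#' @param strand An `ssdsdna_strand`.
#' @return Character scalar (possibly `""`), with attribute `toehold` giving
#'   the lock toehold sequence when one is present.
#' @export
overhang_of <- function(strand) {
  stopifnot(inherits(strand, "ssdsdna_strand"))
  n <- nchar(strand$template)
  covered <- rep(FALSE, n)
  d <- strand$duplex_interval
  if (d[2] > d[1]) covered[(d[1] + 1L):d[2]] <- TRUE
  toehold <- NULL
  for (att in strand$attachments) {
    iv <- att$pairing_interval
    if (iv[2] > iv[1]) covered[(iv[1] + 1L):iv[2]] <- TRUE
    if (!is.null(att$toehold)) toehold <- att$toehold
  }
  exposed <- which(!covered)
  out <- if (length(exposed) == 0L) "" else {
    paste(strsplit(strand$template, "", fixed = TRUE)[[1L]][exposed],
          collapse = "")
  }
  attr(out, "toehold") <- toehold
  out
}

#' Attach an auxiliary oligo to a strand
#'
#' Internal helper used by the file-operation simulator: records an oligo
#' (lock, rename, or block) paired over a template interval. Attachments may
#' not overlap the duplex interval.
#'
#' @param strand An `ssdsdna_strand`.
#' @param oligo Oligo sequence.
#' @param pairing_interval 0-based half-open template interval it covers.
#' @param role One of `"lock"`, `"rename"`, `"block"`.
#' @param new_state State the strand transitions to.
#' @param toehold Unpaired single-stranded part of the oligo, if any.
#' @keywords internal
attach_oligo <- function(strand, oligo, pairing_interval, role, new_state,
                         toehold = NULL) {
  stopifnot(inherits(strand, "ssdsdna_strand"))
  if (pairing_interval[1] < strand$duplex_interval[2] &&
      strand$duplex_interval[1] < pairing_interval[2]) {
    stop("attachment overlaps the duplex interval")
  }
  strand$attachments <- c(strand$attachments, list(list(
    oligo = oligo, pairing_interval = as.integer(pairing_interval),
    role = role, toehold = toehold
  )))
  strand$state <- new_state
  strand
}

## ---- FASTA I/O -------------------------------------------------------------

#' Write sequences to FASTA with key=value header tags
#'
#' Header dialect: `>id key=value key=value`. Used for templates, oligos, and
#' database serialisation (copy counts and roles live in the header).
#'
#' @param seqs Named character vector of sequences (names become ids).
#' @param path Output file path.
#' @param tags Optional data frame / list of per-sequence tag columns.
#' @return Invisibly `path`.
#' @export
write_strand_fasta <- function(seqs, path, tags = NULL) {
  validate_dna(seqs, allow_n = TRUE)
  ids <- names(seqs)
  if (is.null(ids)) ids <- sprintf("seq%06d", seq_along(seqs))
  headers <- ids
  if (!is.null(tags)) {
    tags <- as.data.frame(tags, stringsAsFactors = FALSE)
    stopifnot(nrow(tags) == length(seqs))
    kv <- vapply(seq_len(nrow(tags)), function(i) {
      paste(sprintf("%s=%s", names(tags), unlist(tags[i, ], use.names = FALSE)),
            collapse = " ")
    }, character(1))
    headers <- paste(ids, kv)
  }
  x <- Biostrings::DNAStringSet(seqs)
  names(x) <- headers
  Biostrings::writeXStringSet(x, filepath = path, width = 80L)
  invisible(path)
}

#' Read a key=value tagged FASTA
#'
#' @param path FASTA file path.
#' @return A data frame with columns `id`, `sequence`, and one column per tag
#'   key found in the headers.
#' @export
read_strand_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  full <- names(x)
  parts <- strsplit(full, " ", fixed = TRUE)
  ids <- vapply(parts, `[[`, character(1), 1L)
  out <- data.frame(id = ids, sequence = as.character(x),
                    stringsAsFactors = FALSE, row.names = NULL)
  kvs <- lapply(parts, function(p) {
    p <- p[-1L][grepl("=", p[-1L], fixed = TRUE)]
    if (length(p) == 0L) return(character(0))
    m <- regmatches(p, regexpr("=", p, fixed = TRUE), invert = TRUE)
    setNames(vapply(m, `[[`, character(1), 2L),
             vapply(m, `[[`, character(1), 1L))
  })
  keys <- unique(unlist(lapply(kvs, names)))
  for (k in keys) {
    out[[k]] <- vapply(kvs, function(v) {
      if (k %in% names(v)) v[[k]] else NA_character_
    }, character(1))
  }
  out
}
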