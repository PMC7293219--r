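## Byte <-> codeword codec plus the analytic density and capacity models.
## Each codeword is a distinct L nt sequence holding one byte; the first
## `index_codewords` codewords of every strand encode the strand's ordinal
## index (big-endian base 256) so shuffled strands can be re-ordered.

#' Build a codec specification (byte -> codeword table)
#'
#' Deterministic table of 256 distinct L-mers. The default construction
#' enumerates L-mers in lexicographic order (A < C < G < T), skips any that
#' violate the constraints, and takes the first 256; for `L = 4` with no
#' constraints this is necessarily all 256 4-mers. `method = "random"` instead
#' samples 256 valid L-mers uniformly (seeded), which yields payload sequence
#' diversity closer to real encodings at large L.
#'
#' @param L Codeword length in nt, 4..12.
#' @param max_homopolymer Longest allowed single-base run within a codeword
#'   (`Inf` to disable; note `L = 4` requires all 256 4-mers, so constraints
#'   must be off there).
#' @param method `"lexicographic"` (default) or `"random"`.
#' @param index_codewords Codewords reserved for the strand index (default 5,
#'   sized to index over 1e9 strands: 256^5 > 1e12).
#' @param payload_capacity_nt Payload nt available per strand for codewords
#'   (default 160).
#' @param seed RNG seed for `method = "random"`.
#' @return An object of class `codec_spec` with `L`, `table` (character 256,
#'   names "0".."255"), `index_codewords`, `payload_capacity_nt`.
#' @examples
#' cs <- make_codeword_table(4)
#' cs$table[1:4] # "AAAA" "AAAC" "AAAG" "AAAT"
#' @export
make_codeword_table <- function(L, max_homopolymer = Inf,
                                method = c("lexicographic", "random"),
                                index_codewords = 5L,
                                payload_capacity_nt = 160L, seed = 1L) {
  L <- as.integer(L)
  method <- match.arg(method)
  if (4^L < 256) stop("codeword space exhausted: 4^L < 256")
  if (index_codewords * L > payload_capacity_nt) {
    stop("index codewords exceed payload capacity")
  }
  bases <- c("A", "C", "G", "T")
  ok_run <- function(words) {
    if (!is.finite(max_homopolymer)) return(rep(TRUE, length(words)))
    pat <- paste(sprintf("%s{%d}", bases, max_homopolymer + 1L),
                 collapse = "|")
    !grepl(pat, words)
  }
  idx_to_word <- function(idx) { # 0-based lexicographic rank -> L-mer
    digits <- matrix(0L, nrow = length(idx), ncol = L)
    r <- idx
    for (j in L:1) {
      digits[, j] <- r %% 4L
      r <- r %/% 4L
    }
    apply(digits, 1L, function(d) paste(bases[d + 1L], collapse = ""))
  }
  if (method == "lexicographic") {
    words <- character(0)
    at <- 0L
    chunk <- max(1024L, 256L)
    while (length(words) < 256L && at < 4^L) {
      take <- min(chunk, 4^L - at)
      cand <- idx_to_word(at:(at + take - 1L))
      words <- c(words, cand[ok_run(cand)])
      at <- at + take
    }
    if (length(words) < 256L) stop("codeword space exhausted by constraints")
    tab <- words[1:256]
  } else {
    tab <- character(0)
    seen <- character(0)
    withr::with_seed(seed, {
      tries <- 0L
      while (length(tab) < 256L) {
        tries <- tries + 1L
        if (tries > 10000L) stop("codeword space exhausted by constraints")
        cand <- unique(random_dna(512L, L))
        cand <- cand[ok_run(cand) & !(cand %in% seen)]
        seen <- c(seen, cand)
        tab <- c(tab, cand)
      }
    })
    tab <- tab[1:256]
  }
  structure(
    list(L = L, table = setNames(tab, as.character(0:255)),
         index_codewords = as.integer(index_codewords),
         payload_capacity_nt = as.integer(payload_capacity_nt),
         method = method, max_homopolymer = max_homopolymer),
    class = "codec_spec"
  )
}

#' @export
print.codec_spec <- function(x, ...) {
  cat(sprintf(
    "codec_spec: L = %d nt, 256 codewords (%s), %d index codewords, %d nt payload\n",
    x$L, x$method, x$index_codewords, x$payload_capacity_nt
  ))
  invisible(x)
}

#' Information density of an encoding (bytes per strand)
#'
#' `density = (payload_capacity_nt - index_codewords * L) / L`: the number of
#' data bytes carried by one strand once the strand index is paid for. With
#' the defaults (160 nt payload, 5 index codewords) this is `(160 - 5L)/L`.
#'
#' @param L Codeword length in nt.
#' @param index_codewords Index codewords per strand (default 5).
#' @param payload_capacity_nt Payload nt per strand (default 160).
#' @return Numeric bytes-per-strand (vectorised over `L`).
#' @examples
#' density(4)  # 35
#' density(12) # 100/12
#' @export
density <- function(L, index_codewords = 5, payload_capacity_nt = 160) {
  stopifnot(all(L >= 1))
  (payload_capacity_nt - index_codewords * L) / L
}

#' Total system capacity in bytes
#'
#' `capacity = strands_per_file * n_addresses * density / replicates`: each
#' address hosts one file of `strands_per_file` distinct strands, each strand
#' carries `density` bytes, and physical replication divides the net capacity.
#' Defaults: 1e9 strands per file (about one sequencing run) and 10 physical
#' replicates per strand.
#'
#' @param n_addresses Number of usable file addresses.
#' @param density Bytes per strand (see [density()]).
#' @param strands_per_file Distinct strands per file (default 1e9).
#' @param replicates Physical copies per strand (default 10).
#' @return Numeric capacity in bytes (vectorised).
#' @examples
#' capacity(1, 35) # 3.5e9
#' @export
capacity <- function(n_addresses, density, strands_per_file = 1e9,
                     replicates = 10) {
  stopifnot(all(n_addresses >= 0))
  strands_per_file * n_addresses * density / replicates
}

#' Encode a byte payload into template strands
#'
#' Bytes are chunked into strands of `density(L)` bytes each; every strand is
#' `[index codewords][data codewords][pad][promoter region][address]` with the
#' first `index_codewords` codewords holding the strand ordinal (big-endian
#' base 256). The payload region is padded to `payload_capacity_nt` with `A`s
#' when `payload_capacity_nt` is not a multiple of `L`; partial final strands
#' are padded with byte-0 codewords and the true payload length is recorded in
#' the attached manifest.
#'
#' @param payload Raw vector (bytes) to encode.
#' @param codec A [make_codeword_table()] spec.
#' @param address Address sequence appended at the 3' terminus.
#' @param promoter_region Promoter-region sequence (default
#'   [default_promoter_region()]).
#' @return Character vector of template sequences with attribute `manifest`
#'   (list: `L`, `payload_length`, `index_codewords`, `payload_capacity_nt`,
#'   `n_strands`, `address`).
#' @export
encode <- function(payload, codec, address,
                   promoter_region = default_promoter_region()) {
  stopifnot(is.raw(payload), inherits(codec, "codec_spec"))
  validate_dna(address)
  L <- codec$L
  n_cw <- codec$payload_capacity_nt %/% L
  data_cw <- n_cw - codec$index_codewords
  if (data_cw <= 0) stop("no payload codewords available at this L")
  manifest <- list(
    L = L, payload_length = length(payload),
    index_codewords = codec$index_codewords,
    payload_capacity_nt = codec$payload_capacity_nt,
    address = address
  )
  if (length(payload) == 0L) {
    out <- character(0)
    manifest$n_strands <- 0L
    attr(out, "manifest") <- manifest
    return(out)
  }
  n_strands <- ceiling(length(payload) / data_cw)
  if (n_strands > 256^codec$index_codewords) stop("index overflow")
  manifest$n_strands <- as.integer(n_strands)
  ## pad payload bytes to a whole number of strands with byte 0
  padded <- c(as.integer(payload),
              rep(0L, n_strands * data_cw - length(payload)))
  data_mat <- matrix(codec$table[padded + 1L], nrow = n_strands, byrow = TRUE)
  ## index codewords: big-endian base-256 ordinal (0-based)
  ord <- seq_len(n_strands) - 1L
  idx_mat <- matrix("", nrow = n_strands, ncol = codec$index_codewords)
  r <- ord
  for (j in codec$index_codewords:1) {
    idx_mat[, j] <- codec$table[(r %% 256L) + 1L]
    r <- r %/% 256L
  }
  pad_nt <- strrep("A", codec$payload_capacity_nt - n_cw * L)
  body <- apply(cbind(idx_mat, data_mat), 1L, paste, collapse = "")
  out <- paste0(body, pad_nt, promoter_region, address)
  attr(out, "manifest") <- manifest
  out
}

#' Decode template strands back to bytes
#'
#' Strands are sorted by their decoded index codewords, data codewords are
#' mapped back through the inverse table, and trailing pad bytes are stripped
#' using the manifest's true payload length.
#'
#' @param strands Character vector of templates (any order), or the result of
#'   [encode()] (its manifest is then picked up automatically).
#' @param codec The [make_codeword_table()] spec used to encode.
#' @param manifest Manifest list from [encode()]; defaults to
#'   `attr(strands, "manifest")`.
#' @return Raw vector: the original payload.
#' @export
decode <- function(strands, codec, manifest = attr(strands, "manifest")) {
  stopifnot(inherits(codec, "codec_spec"))
  if (is.null(manifest)) stop("decode requires the encode manifest")
  if (length(strands) == 0L) return(raw(0))
  L <- codec$L
  n_cw <- codec$payload_capacity_nt %/% L
  inv <- setNames(as.integer(names(codec$table)), codec$table)
  slots <- vapply(0:(n_cw - 1L), function(k) {
    substr(strands, k * L + 1L, (k + 1L) * L)
  }, character(length(strands)))
  slots <- matrix(slots, nrow = length(strands))
  vals <- matrix(inv[slots], nrow = length(strands))
  if (anyNA(vals)) {
    bad <- which(is.na(vals), arr.ind = TRUE)[1L, ]
    stop(sprintf("uncorrectable codeword in strand %d, slot %d",
                 bad[1L], bad[2L]))
  }
  ic <- codec$index_codewords
  idx <- vals[, seq_len(ic), drop = FALSE] %*% (256^((ic - 1L):0))
  if (anyDuplicated(idx)) stop("duplicate strand indices")
  ord <- order(idx)
  data_vals <- vals[ord, (ic + 1L):n_cw, drop = FALSE]
  bytes <- as.vector(t(data_vals))
  bytes <- bytes[seq_len(manifest$payload_length)]
  as.raw(bytes)
}

#' Layout sized to a codec's payload capacity
#'
#' Convenience: a [template_layout()] whose payload region exactly fits
#' `payload_capacity_nt` codeword nt (total = payload + 23 + 20 by default).
#'
#' @param codec A `codec_spec`.
#' @param address_length,promoter_region_length As in [template_layout()].
#' @return A `template_layout`.
#' @export
codec_layout <- function(codec, address_length = 20L,
                         promoter_region_length = 23L) {
  template_layout(
    total_length = codec$payload_capacity_nt + address_length +
      promoter_region_length,
    address_length = address_length,
    promoter_region_length = promoter_region_length
  )
}
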