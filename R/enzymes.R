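#' @importFrom rlang %||% abort warn .data
#' @importFrom generics tidy glance
#' @importFrom ggplot2 autoplot
NULL

the_registry <- new.env(parent = emptyenv())

#' Restriction enzyme registry
#'
#' The shipped registry (`inst/extdata/enzymes.tsv`, an editable
#' tab-separated file) covers the enzymes relevant to MoClo, BioBrick,
#' BglBrick and integration-cassette compatibility: the type-IIS enzymes
#' BsaI and BsmBI (4-nt 5' overhangs), NotI, and the palindromic scanning
#' enzymes EcoRI, XbaI, SpeI, PstI, BglII, BamHI, XhoI. Cut offsets are
#' stored relative to the 3' end of the top-strand recognition motif;
#' `overhang_len = cut_offset_bottom - cut_offset_top` (negative for
#' 3'-overhang cutters such as PstI, which are scanned but cannot be used
#' for digestion).
#'
#' @param path Optional path to an alternative registry file with the same
#'   columns (`name`, `recognition`, `cut_offset_top`, `cut_offset_bottom`).
#' @return A tibble with columns `name`, `recognition`, `cut_offset_top`,
#'   `cut_offset_bottom`, `overhang_len`.
#' @export
enzyme_registry <- function(path = NULL) {
  if (is.null(path)) {
    if (!is.null(the_registry$default)) return(the_registry$default)
    path <- system.file("extdata", "enzymes.tsv", package = "mocloforge")
    cache <- TRUE
  } else {
    cache <- FALSE
  }
  reg <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  need <- c("name", "recognition", "cut_offset_top", "cut_offset_bottom")
  if (!all(need %in% names(reg))) {
    abort(sprintf("Enzyme registry must have columns: %s.",
                  paste(need, collapse = ", ")),
          class = c("mocloforge_error_validation", "mocloforge_error"))
  }
  reg$recognition <- toupper(reg$recognition)
  bad <- grepl("[^ACGT]", reg$recognition)
  if (any(bad)) {
    abort(sprintf("Degenerate or invalid recognition motif(s): %s.",
                  paste(reg$name[bad], collapse = ", ")),
          class = c("mocloforge_error_validation", "mocloforge_error"))
  }
  reg$overhang_len <- reg$cut_offset_bottom - reg$cut_offset_top
  out <- tibble::as_tibble(reg[, c(need, "overhang_len")])
  if (cache) the_registry$default <- out
  out
}

#' @rdname enzyme_registry
#' @param name Enzyme name (e.g. `"BsmBI"`).
#' @return `enzyme()` returns a one-row tibble for the named enzyme.
#' @export
enzyme <- function(name, path = NULL) {
  reg <- enzyme_registry(path)
  hit <- reg[reg$name == name, ]
  if (nrow(hit) != 1L) {
    abort(sprintf("Unknown enzyme '%s' (registry has: %s).",
                  name, paste(reg$name, collapse = ", ")),
          class = c("mocloforge_error_validation", "mocloforge_error"))
  }
  hit
}

# internal: normalise enzyme argument (name(s) or registry rows) to tibble
as_enzymes <- function(enzymes) {
  if (is.character(enzymes)) {
    return(dplyr::bind_rows(lapply(enzymes, enzyme)))
  }
  if (is.data.frame(enzymes) && nrow(enzymes) >= 1L) {
    return(tibble::as_tibble(enzymes))
  }
  abort("`enzymes` must be enzyme names or registry rows (non-empty).",
        class = c("mocloforge_error_validation", "mocloforge_error"))
}

# internal: 1-based fixed-string match starts of `motif` in `subject`
fixed_starts <- function(subject, motif) {
  m <- gregexpr(motif, subject, fixed = TRUE)[[1]]
  if (m[1] == -1L) integer(0) else as.integer(m)
}

#' Scan a sequence for recognition sites
#'
#' Reports every occurrence of every recognition motif on both strands.
#' A bottom-strand occurrence (the motif's reverse complement found on the
#' top strand) is reported with strand `"-"`; palindromic motifs are
#' reported once, with strand `"+"`. Circular inputs are scanned across
#' the origin: a hit spanning the origin is reported with `start < length`
#' and `end > length`. Coordinates are 0-based, half-open, on the input's
#' top strand.
#'
#' @param x A `dna` object or DNA string.
#' @param enzymes Enzyme names or registry rows; defaults to the full
#'   shipped registry.
#' @return A tibble with columns `enzyme`, `start`, `end`, `strand`,
#'   sorted by enzyme, then start.
#' @examples
#' scan_sites("CCAGATCTGG", "BglII")
#' @export
scan_sites <- function(x, enzymes = enzyme_registry()) {
  x <- as_dna(x)
  reg <- as_enzymes(enzymes)
  s <- seq_chr(x)
  L <- nchar(s)
  circular <- dna_topology(x) == "circular"
  rows <- lapply(seq_len(nrow(reg)), function(i) {
    motif <- reg$recognition[i]
    mlen <- nchar(motif)
    subject <- if (circular && mlen > 1L) {
      paste0(s, substr(s, 1L, mlen - 1L))
    } else {
      s
    }
    rcm <- revcomp(motif)
    plus <- fixed_starts(subject, motif)
    if (motif == rcm) {
      minus <- integer(0)
    } else {
      minus <- fixed_starts(subject, rcm)
    }
    keep <- function(st) st[st <= L]  # dedupe wrapped duplicates
    plus <- keep(plus)
    minus <- keep(minus)
    tibble::tibble(
      enzyme = reg$name[i],
      start = c(plus, minus) - 1L,
      end = c(plus, minus) - 1L + mlen,
      strand = rep(c("+", "-"), c(length(plus), length(minus)))
    )
  })
  out <- dplyr::bind_rows(rows)
  dplyr::arrange(out, .data$enzyme, .data$start, .data$strand)
}
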