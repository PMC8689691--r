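#' DNA sequence with explicit topology
#'
#' A `dna` object is a validated single string over the strict alphabet
#' `A`, `C`, `G`, `T`, carrying a `topology` attribute of `"linear"` or
#' `"circular"`. Lowercase input is uppercased on ingestion; degenerate
#' IUPAC codes and RNA (`U`) are rejected. Circular sequences have no
#' distinguished origin: every operation in the package that accepts a
#' circular `dna` is rotation-invariant.
#'
#' @param bases A single character string of DNA bases (case-insensitive).
#' @param topology `"linear"` (default) or `"circular"`.
#' @return A `dna` object (character scalar with class and topology).
#' @examples
#' dna("atgCCC")
#' dna("ATGC", topology = "circular")
#' @export
dna <- function(bases, topology = c("linear", "circular")) {
  topology <- match.arg(topology)
  if (inherits(bases, "dna")) {
    return(structure(unclass(bases), topology = topology, class = "dna"))
  }
  if (!is.character(bases) || length(bases) != 1L || is.na(bases)) {
    rlang::abort("`bases` must be a single character string.",
                 class = c("mocloforge_error_validation", "mocloforge_error"))
  }
  up <- toupper(bases)
  if (!nzchar(up)) {
    rlang::abort("DNA sequence must be non-empty.",
                 class = c("mocloforge_error_validation", "mocloforge_error"))
  }
  bad <- gsub("[ACGT]", "", up)
  if (nzchar(bad)) {
    rlang::abort(
      sprintf("Invalid DNA character(s): %s (only A, C, G, T are allowed).",
              paste(unique(strsplit(bad, "")[[1]]), collapse = ", ")),
      class = c("mocloforge_error_validation", "mocloforge_error")
    )
  }
  structure(up, topology = topology, class = "dna")
}

#' @rdname dna
#' @param x Object to test or coerce.
#' @export
is_dna <- function(x) inherits(x, "dna")

#' @rdname dna
#' @export
as_dna <- function(x, topology = c("linear", "circular")) {
  if (is_dna(x) && missing(topology)) return(x)
  dna(x, topology = if (is_dna(x)) dna_topology(x) else match.arg(topology))
}

#' @rdname dna
#' @export
dna_topology <- function(x) {
  if (!is_dna(x)) return("linear")
  attr(x, "topology") %||% "linear"
}

#' @rdname dna
#' @export
dna_length <- function(x) nchar(unclass(as_dna(x)))

#' @export
print.dna <- function(x, ...) {
  s <- unclass(x)
  shown <- if (nchar(s) > 60) paste0(substr(s, 1, 57), "...") else s
  cat(sprintf("<dna %s, %d nt> %s\n", dna_topology(x), nchar(s), shown))
  invisible(x)
}

#' @export
as.character.dna <- function(x, ...) as.vector(unclass(x))

# internal: plain-string view (no attributes) regardless of input class
seq_chr <- function(x) {
  if (is_dna(x)) as.vector(unclass(x)) else as.vector(unclass(as_dna(x)))
}

#' Reverse complement
#'
#' Watson-Crick reverse complement. Topology is preserved.
#'
#' @param x A `dna` object or a plain DNA string.
#' @return For `dna` input, a `dna` of the same topology; for character
#'   input, a character string.
#' @examples
#' revcomp("ATGC")  # "GCAT"
#' revcomp("AGATCT")  # palindromic
#' @export
revcomp <- function(x) {
  keep <- is_dna(x)
  s <- seq_chr(x)
  out <- chartr("ACGT", "TGCA", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
  if (keep) dna(out, topology = dna_topology(x)) else out
}

#' Wallace-rule melting temperature
#'
#' The Wallace (2 + 4) rule: `Tm = 2 * (#A + #T) + 4 * (#G + #C)` degrees
#' Celsius. This is the ranking metric used for primer binding regions; no
#' nearest-neighbour or salt correction is applied.
#'
#' @param x A linear `dna` object or DNA string, length >= 1.
#' @return Melting temperature in degrees C (integer-valued numeric).
#' @examples
#' wallace_tm("AATT")  # 8
#' wallace_tm("GGCC")  # 16
#' @export
wallace_tm <- function(x) {
  s <- seq_chr(x)
  n_gc <- nchar(gsub("[AT]", "", s))
  n_at <- nchar(s) - n_gc
  2 * n_at + 4 * n_gc
}

#' GC fraction
#'
#' @param x A `dna` object or DNA string, length >= 1.
#' @return Fraction of G + C bases, in `[0, 1]`.
#' @examples
#' gc_fraction("ATGC")  # 0.5
#' @export
gc_fraction <- function(x) {
  s <- seq_chr(x)
  nchar(gsub("[AT]", "", s)) / nchar(s)
}
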