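#' Sticky-end conflict predicate
#'
#' Two 4-nt overhangs conflict when they share at least `threshold`
#' positionally matching nucleotides, comparing both the forward sequence
#' and the reverse complement. Conflicting overhangs can cross-ligate in a
#' Golden Gate reaction and scramble assembly order; the designer requires
#' every junction pair (and every junction against its own reverse
#' complement) to be conflict-free.
#'
#' @param a,b 4-nt top-strand overhang strings.
#' @param threshold Minimum number of matching positions that counts as a
#'   conflict (default 3).
#' @return Logical scalar; symmetric in `a` and `b`.
#' @examples
#' ends_conflict("AACG", "AACT")  # TRUE, 3 forward matches
#' ends_conflict("AAAA", "CCCC")  # FALSE
#' @export
ends_conflict <- function(a, b, threshold = 3L) {
  a <- toupper(a); b <- toupper(b)
  if (nchar(a) != 4L || nchar(b) != 4L) {
    abort("Sticky ends must be exactly 4 nt.",
          class = c("mocloforge_error_validation", "mocloforge_error"))
  }
  n_positional_matches(a, b) >= threshold ||
    n_positional_matches(a, revcomp(b)) >= threshold
}

# internal: positional matches between equal-length strings
n_positional_matches <- function(a, b) {
  sum(utf8ToInt(a) == utf8ToInt(b))
}

# internal: is `o` unable to coexist with the set `members`?
conflicts_with_set <- function(o, members, threshold) {
  if (n_positional_matches(o, revcomp(o)) >= threshold) return(TRUE)
  any(vapply(members, function(m) ends_conflict(o, m, threshold), logical(1)))
}
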