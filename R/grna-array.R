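# MultigRNA-style single-step gRNA array design.
#
# An N-spacer array is built from N-1 PCR fragments amplified off one
# scaffold+separator template. Intermediate spacers (2..N-1) are split
# between consecutive fragments at a 4-nt overhang window chosen as close
# to the spacer's centre as possible while keeping all junction overhangs
# (including the two destination-vector overhangs) mutually conflict-free.

TAIL_FLANK <- "AA"
TAIL_SPACER <- "A"
BSMBI_MOTIF <- "CGTCTC"

tail_prefix <- function(flank = TAIL_FLANK, spacer_base = TAIL_SPACER) {
  paste0(flank, BSMBI_MOTIF, spacer_base)
}

#' Specify a gRNA array design problem
#'
#' Bundles the three inputs of the array designer: the ordered 20-nt
#' spacers to multiplex (2 to 12), the two BsmBI-created overhangs of the
#' destination vector (5'->3'), and the forward/reverse primer binding
#' parts taken from the PCR template (scaffold + separator).
#'
#' @param spacers Character vector or list of `dna` of exactly 20-nt
#'   spacer sequences, in array order (2 to 12 of them).
#' @param vector_end_5,vector_end_3 4-nt destination-vector overhangs,
#'   given 5'->3' on the top strand.
#' @param binding_fwd,binding_rev Primer binding regions on the template
#'   (forward: top strand at the scaffold start; reverse: reverse
#'   complement of the separator end).
#' @param conflict_threshold Matching-nucleotide count that defines a
#'   sticky-end conflict (default 3; see [ends_conflict()]).
#' @param spacer_len Expected spacer length (default 20 nt).
#' @return An `array_spec` object.
#' @export
array_spec <- function(spacers, vector_end_5, vector_end_3,
                       binding_fwd, binding_rev,
                       conflict_threshold = 3L, spacer_len = 20L) {
  spacers <- vapply(spacers, function(s) seq_chr(as_dna(s)), character(1))
  n <- length(spacers)
  if (n < 2L || n > 12L) {
    abort(sprintf("An array takes 2 to 12 spacers; got %d.", n),
          class = c("mocloforge_error_validation", "mocloforge_error"))
  }
  if (any(nchar(spacers) != spacer_len)) {
    abort(sprintf("Every spacer must be exactly %d nt.", spacer_len),
          class = c("mocloforge_error_validation", "mocloforge_error"))
  }
  ends <- c(vector_end_5 = vector_end_5, vector_end_3 = vector_end_3)
  for (e in ends) {
    e <- seq_chr(as_dna(e))
    if (nchar(e) != 4L) {
      abort("Vector overhangs must be 4 nt.",
            class = c("mocloforge_error_validation", "mocloforge_error"))
    }
  }
  if (conflict_threshold < 1L) {
    abort("`conflict_threshold` must be >= 1.",
          class = c("mocloforge_error_validation", "mocloforge_error"))
  }
  structure(
    list(
      spacers = unname(spacers),
      vector_end_5 = toupper(vector_end_5),
      vector_end_3 = toupper(vector_end_3),
      binding_fwd = seq_chr(as_dna(binding_fwd)),
      binding_rev = seq_chr(as_dna(binding_rev)),
      conflict_threshold = as.integer(conflict_threshold),
      spacer_len = as.integer(spacer_len)
    ),
    class = "array_spec"
  )
}

#' @export
print.array_spec <- function(x, ...) {
  cat(sprintf("<array_spec> %d spacers, vector ends %s/%s, threshold %d\n",
              length(x$spacers), x$vector_end_5, x$vector_end_3,
              x$conflict_threshold))
  invisible(x)
}

# internal: candidate split offsets for a 20-nt spacer, ordered by
# distance of the overhang window [s, s+4) from centre (|s - 8|), ties
# toward smaller s; s ranges 1..len-5 so >= 1 nt remains on each flank.
candidate_offsets <- function(spacer_len = 20L) {
  centre <- (spacer_len - 4L) %/% 2L
  s <- seq.int(1L, spacer_len - 5L)
  s[order(abs(s - centre), s)]
}

#' Choose conflict-free split positions for the intermediate spacers
#'
#' Depth-first greedy search with chronological backtracking over the
#' intermediate spacers in array order. For each spacer the candidate
#' 4-nt overhang windows are tried from the spacer's centre outward; a
#' candidate is feasible when its overhang is not self-conflicting
#' (against its own reverse complement) and does not conflict with either
#' vector overhang or any overhang chosen so far. Deterministic for a
#' given spec.
#'
#' @param spec An [array_spec()].
#' @return A tibble of splits with columns `spacer` (index, 2..N-1),
#'   `offset` (0-based start of the overhang window within the spacer),
#'   and `overhang`; zero rows when N = 2. Raises
#'   `mocloforge_error_infeasible` naming the first unsatisfiable spacer
#'   when no conflict-free assignment exists.
#' @export
find_junctions <- function(spec) {
  stopifnot(inherits(spec, "array_spec"))
  th <- spec$conflict_threshold
  v5 <- spec$vector_end_5
  v3 <- spec$vector_end_3
  if (n_positional_matches(v5, revcomp(v5)) >= th ||
      n_positional_matches(v3, revcomp(v3)) >= th) {
    abort("A vector overhang conflicts with its own reverse complement.",
          class = c("mocloforge_error_infeasible", "mocloforge_error"))
  }
  if (ends_conflict(v5, v3, th)) {
    abort("The two vector overhangs conflict with each other.",
          class = c("mocloforge_error_infeasible", "mocloforge_error"))
  }
  n <- length(spec$spacers)
  mids <- if (n > 2L) seq.int(2L, n - 1L) else integer(0)
  empty <- tibble::tibble(spacer = integer(0), offset = integer(0),
                          overhang = character(0))
  if (!length(mids)) return(empty)

  offsets <- candidate_offsets(spec$spacer_len)
  deepest <- 0L
  chosen_offsets <- integer(length(mids))
  chosen_ends <- character(length(mids))

  solve <- function(level) {
    if (level > length(mids)) return(TRUE)
    deepest <<- max(deepest, level)
    sp <- spec$spacers[mids[level]]
    members <- c(v5, v3, chosen_ends[seq_len(level - 1L)])
    for (s in offsets) {
      o <- substr(sp, s + 1L, s + 4L)
      if (!conflicts_with_set(o, members, th)) {
        chosen_offsets[level] <<- s
        chosen_ends[level] <<- o
        if (solve(level + 1L)) return(TRUE)
      }
    }
    FALSE
  }
  if (!solve(1L)) {
    abort(sprintf(
      "No conflict-free split assignment exists; spacer %d is unsatisfiable.",
      mids[deepest]),
      class = c("mocloforge_error_infeasible", "mocloforge_error"), spacer = mids[deepest])
  }
  tibble::tibble(spacer = mids, offset = chosen_offsets,
                 overhang = chosen_ends)
}

#' Emit the PCR primer pairs of an array design
#'
#' Builds the N-1 primer pairs implied by the chosen splits. The forward
#' tail of fragment 1 carries the 5' vector overhang and the complete
#' first spacer; the forward tail of fragment k carries the right part of
#' spacer k from its overhang window onward; reverse tails carry the
#' reverse complement of the left part of the following spacer through
#' its overhang window (the last fragment's reverse tail carries the
#' complete last spacer plus the 3' vector overhang). After BsmBI
#' digestion of each amplicon, fragment k's overhangs equal junctions k
#' and k + 1, so the ligated insert concatenates the spacers and template
#' copies with zero inserted or deleted bases; [verify_array()] checks
#' this round trip, which is the normative contract.
#'
#' @param spec An [array_spec()].
#' @param splits Split tibble from [find_junctions()].
#' @param flank,spacer_base Tail bases flanking the BsmBI recognition site
#'   (defaults `"AA"` and `"A"`).
#' @return An `array_design` object.
#' @export
emit_primers <- function(spec, splits, flank = TAIL_FLANK,
                         spacer_base = TAIL_SPACER) {
  stopifnot(inherits(spec, "array_spec"))
  n <- length(spec$spacers)
  if (nrow(splits) != max(0L, n - 2L)) {
    abort("`splits` does not match the spec (need one split per intermediate spacer).",
          class = c("mocloforge_error_validation", "mocloforge_error"))
  }
  pre <- tail_prefix(flank, spacer_base)
  sp <- spec$spacers
  off <- stats::setNames(splits$offset, splits$spacer)

  junctions <- c(spec$vector_end_5, splits$overhang, spec$vector_end_3)

  frag <- lapply(seq_len(n - 1L), function(k) {
    fwd_payload <- if (k == 1L) {
      paste0(spec$vector_end_5, sp[1])
    } else {
      s <- off[[as.character(k)]]
      substr(sp[k], s + 1L, spec$spacer_len)
    }
    rev_payload <- if (k == n - 1L) {
      revcomp(paste0(sp[n], spec$vector_end_3))
    } else {
      s <- off[[as.character(k + 1L)]]
      revcomp(substr(sp[k + 1L], 1L, s + 4L))
    }
    list(
      fragment = k,
      fwd_tail = paste0(pre, fwd_payload),
      rev_tail = paste0(pre, rev_payload)
    )
  })

  primer_row <- function(k, orientation, tail, binding) {
    tibble::tibble(
      name = sprintf("frag%d_%s", k, orientation),
      fragment = k,
      orientation = if (orientation == "F") "forward" else "reverse",
      sequence = paste0(tail, binding),
      tail = tail,
      binding = binding,
      length = nchar(tail) + nchar(binding),
      gc = gc_fraction(binding),
      tm = wallace_tm(binding)
    )
  }
  primers <- dplyr::bind_rows(lapply(frag, function(f) {
    dplyr::bind_rows(
      primer_row(f$fragment, "F", f$fwd_tail, spec$binding_fwd),
      primer_row(f$fragment, "R", f$rev_tail, spec$binding_rev)
    )
  }))

  structure(
    list(spec = spec, splits = splits, junctions = junctions,
         primers = primers),
    class = "array_design"
  )
}

#' Design a multiplexed gRNA array in one call
#'
#' Runs [find_junctions()] then [emit_primers()].
#'
#' @inheritParams emit_primers
#' @inheritParams array_spec
#' @return An `array_design` object.
#' @export
design_grna_array <- function(spacers, vector_end_5, vector_end_3,
                              binding_fwd, binding_rev,
                              conflict_threshold = 3L,
                              flank = TAIL_FLANK, spacer_base = TAIL_SPACER) {
  spec <- array_spec(spacers, vector_end_5, vector_end_3,
                     binding_fwd, binding_rev, conflict_threshold)
  emit_primers(spec, find_junctions(spec), flank = flank,
               spacer_base = spacer_base)
}

#' @export
print.array_design <- function(x, ...) {
  cat(sprintf(
    "<array_design> %d spacers -> %d PCR fragments, %d split(s)\n",
    length(x$spec$spacers), max(x$primers$fragment), nrow(x$splits)))
  cat("junctions:", paste(x$junctions, collapse = " "), "\n")
  invisible(x)
}

#' @export
tidy.array_design <- function(x, ...) x$primers

#' @export
glance.array_design <- function(x, ...) {
  centre <- (x$spec$spacer_len - 4L) %/% 2L
  tibble::tibble(
    n_spacers = length(x$spec$spacers),
    n_fragments = max(x$primers$fragment),
    n_splits = nrow(x$splits),
    max_centre_deviation = if (nrow(x$splits)) max(abs(x$splits$offset - centre)) else 0L,
    conflict_threshold = x$spec$conflict_threshold
  )
}

#' Plot the split layout of an array design
#'
#' One horizontal bar per spacer with the chosen 4-nt overhang window
#' highlighted; the dashed line marks the centred window position.
#'
#' @param object An `array_design`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.array_design <- function(object, ...) {
  n <- length(object$spec$spacers)
  len <- object$spec$spacer_len
  centre <- (len - 4L) %/% 2L
  bars <- tibble::tibble(spacer = seq_len(n))
  win <- object$splits
  p <- ggplot2::ggplot(bars) +
    ggplot2::geom_segment(ggplot2::aes(x = 0, xend = len,
                                       y = .data$spacer, yend = .data$spacer),
                          linewidth = 3, colour = "grey80") +
    ggplot2::geom_vline(xintercept = c(centre, centre + 4), linetype = "dashed",
                        colour = "grey50") +
    ggplot2::scale_y_reverse(breaks = seq_len(n)) +
    ggplot2::labs(x = "position in spacer (nt)", y = "spacer",
                  title = "gRNA array split layout")
  if (nrow(win)) {
    p <- p + ggplot2::geom_segment(
      data = win,
      ggplot2::aes(x = .data$offset, xend = .data$offset + 4,
                   y = .data$spacer, yend = .data$spacer),
      linewidth = 3, colour = "#d95f02")
  }
  p
}

#' Verify an array design by simulated Golden Gate assembly
#'
#' Simulates each fragment's PCR on the template, digests all amplicons
#' and the destination vector with BsmBI, runs [golden_gate()], extracts
#' the insert between the backbone junctions, and compares it with the
#' expected concatenation
#' `spacer_1 + (scaffold + separator + spacer_i) for i = 2..N`.
#'
#' @param design An `array_design`.
#' @param template The linear scaffold + separator template (`dna` or
#'   string) containing both binding regions.
#' @param destination A circular destination vector with two BsmBI sites
#'   releasing a dropout and exposing the spec's vector overhangs.
#' @return The reconstructed insert as a linear `dna` (invisibly also the
#'   full product in attribute `"product"`). Any ambiguity or mismatch
#'   raises a detailed error.
#' @export
verify_array <- function(design, template, destination) {
  stopifnot(inherits(design, "array_design"))
  template <- as_dna(template)
  s <- seq_chr(template)
  if (length(fixed_starts(s, design$spec$binding_fwd)) != 1L ||
      length(fixed_starts(s, revcomp(design$spec$binding_rev))) != 1L) {
    abort("Binding parts not found (exactly once) in the provided template.",
          class = c("mocloforge_error_validation", "mocloforge_error"))
  }
  pr <- design$primers
  amplicons <- lapply(seq_len(max(pr$fragment)), function(k) {
    fwd <- pr[pr$fragment == k & pr$orientation == "forward", ]
    rev <- pr[pr$fragment == k & pr$orientation == "reverse", ]
    simulate_pcr(template, fwd, rev)
  })
  names(amplicons) <- paste0("amplicon", seq_along(amplicons))
  res <- golden_gate(c(amplicons, list(destination = as_dna(destination, "circular"))),
                     enzyme = "BsmBI")
  insert <- extract_insert(res$product, destination,
                           design$spec$vector_end_5, design$spec$vector_end_3)
  n <- length(design$spec$spacers)
  expected <- paste0(design$spec$spacers[1],
                     paste0(s, design$spec$spacers[-1], collapse = ""))
  if (insert != expected) {
    d <- first_difference(insert, expected)
    abort(sprintf(
      paste0("Reconstructed insert differs from the expected array at ",
             "position %d: got '%s', expected '%s' (lengths %d vs %d)."),
      d, substr(insert, d, d + 9L), substr(expected, d, d + 9L),
      nchar(insert), nchar(expected)),
      class = c("mocloforge_error_verification", "mocloforge_error"))
  }
  out <- dna(insert)
  attr(out, "product") <- res$product
  out
}

# internal: locate the backbone (vend3 + backbone core + vend5) in the
# circular product and return the remaining arc (the insert, junction
# 4-mers excluded).
extract_insert <- function(product, destination, vend5, vend3) {
  frs <- digest(as_dna(destination, "circular"), "BsmBI", label = "dest")
  carries_site <- vapply(seq_len(nrow(frs)), function(i) {
    full <- paste0(frs$left_end[i], frs$core[i], frs$right_end[i])
    nrow(scan_sites(dna(full), "BsmBI")) > 0L
  }, logical(1))
  backbone <- frs[!carries_site, ]
  if (nrow(backbone) != 1L) {
    abort("Destination vector does not digest into one backbone and one dropout.",
          class = c("mocloforge_error_validation", "mocloforge_error"))
  }
  needle <- paste0(backbone$left_end, backbone$core, backbone$right_end)
  P <- seq_chr(product)
  L <- nchar(P)
  for (cand in c(P, revcomp(P))) {
    pos <- fixed_starts(paste0(cand, cand), needle)
    pos <- pos[pos <= L]
    if (length(pos) == 1L) {
      start <- pos + nchar(needle)
      len <- L - nchar(needle)
      return(substr(paste0(cand, cand), start, start + len - 1L))
    }
  }
  abort("Backbone arc not found exactly once in the assembled product.",
        class = c("mocloforge_error_verification", "mocloforge_error"))
}

# internal: 1-based position of the first differing character
first_difference <- function(a, b) {
  n <- min(nchar(a), nchar(b))
  if (n > 0L) {
    av <- utf8ToInt(substr(a, 1L, n))
    bv <- utf8ToInt(substr(b, 1L, n))
    w <- which(av != bv)
    if (length(w)) return(w[1])
  }
  n + 1L
}
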