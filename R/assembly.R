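# In silico type-IIS digestion and one-pot Golden Gate ligation.
#
# Fragment bookkeeping convention: both physical ends of a junction are
# represented by the same top-strand 4-mer, so a fragment's full top strand
# is left_end + core + right_end and ligation matches right_end of one
# fragment to an equal left_end of another. This counts each junction's
# overhang exactly once when fragment lengths are summed.

# internal: substring of a circular sequence, 0-based half-open, wrapping
circ_substr <- function(s, from, to) {
  L <- nchar(s)
  from <- from %% L
  d <- paste0(s, s)
  substr(d, from + 1L, from + (to - from))
}

# internal: cut events (top-strand cut position t, 0-based; overhang
# window [t, t + ovl)) for one enzyme on one molecule
cut_positions <- function(x, enz) {
  s <- seq_chr(x)
  L <- nchar(s)
  circular <- dna_topology(x) == "circular"
  hits <- scan_sites(x, enz)
  if (nrow(hits) == 0L) return(integer(0))
  t_plus <- hits$end[hits$strand == "+"] + enz$cut_offset_top
  t_minus <- hits$start[hits$strand == "-"] - enz$cut_offset_bottom
  t <- c(t_plus, t_minus)
  ovl <- enz$overhang_len
  if (circular) {
    t <- t %% L
  } else if (any(t < 0L | t + ovl > L)) {
    abort(sprintf(
      "%s cut window falls outside the linear molecule.", enz$name),
      class = c("mocloforge_error_assembly", "mocloforge_error"))
  }
  sort(unique(as.integer(t)))
}

#' Digest a molecule with one enzyme
#'
#' Computes cut positions from recognition-site locations, strands and the
#' enzyme's cut offsets, and returns the resulting fragments with their
#' 4-nt 5' overhangs. A circular molecule with k sites yields k fragments;
#' a linear molecule with k sites yields k + 1 fragments (terminal ends
#' blunt, reported as `NA`). Total length, counting each junction's
#' overhang once, equals the input length.
#'
#' @param x A `dna` object (linear or circular).
#' @param enzyme Enzyme name or registry row. Must leave 5' overhangs
#'   (3'-overhang cutters such as PstI are scanning-only).
#' @param label Provenance label recorded on each fragment.
#' @return A tibble with columns `fragment`, `left_end`, `core`,
#'   `right_end`, `provenance` (`left_end`/`right_end` are 4-nt top-strand
#'   overhangs, or `NA` for blunt ends).
#' @examples
#' digest(dna("AAACGTCTCATTTTGGGGG"), "BsmBI")
#' @export
digest <- function(x, enzyme, label = "molecule") {
  x <- as_dna(x)
  enz <- as_enzymes(enzyme)
  if (nrow(enz) != 1L) {
    abort("`digest()` takes exactly one enzyme.",
          class = c("mocloforge_error_validation", "mocloforge_error"))
  }
  if (enz$overhang_len < 0L) {
    abort(sprintf("%s leaves a 3' overhang; only 5'-overhang digestion is modeled.",
                  enz$name),
          class = c("mocloforge_error_validation", "mocloforge_error"))
  }
  s <- seq_chr(x)
  L <- nchar(s)
  ovl <- enz$overhang_len
  circular <- dna_topology(x) == "circular"
  t <- cut_positions(x, enz)
  k <- length(t)

  frag_tbl <- function(left, core, right) {
    tibble::tibble(
      fragment = seq_along(core),
      left_end = left, core = core, right_end = right,
      provenance = if (length(core)) paste0(label, ":frag", seq_along(core)) else character(0)
    )
  }

  if (k == 0L) {
    if (circular) {
      out <- frag_tbl(character(0), character(0), character(0))
      attr(out, "uncut") <- TRUE
      return(out)
    }
    return(frag_tbl(NA_character_, s, NA_character_))
  }

  # overlapping overhang windows are an ambiguous digest
  gaps <- if (k > 1L) diff(t) else numeric(0)
  if (circular) gaps <- c(gaps, t[1] + L - t[k])
  if (any(gaps < ovl) || (circular && k == 1L && L < ovl)) {
    abort("Ambiguous digest: overlapping cut windows.",
          class = c("mocloforge_error_assembly", "mocloforge_error"))
  }

  win <- vapply(t, function(p) circ_substr(s, p, p + ovl), character(1))
  if (circular) {
    nxt <- c(seq_len(k)[-1], 1L)
    core <- vapply(seq_len(k), function(i) {
      to <- if (i == k) t[1] + L else t[i + 1L]
      circ_substr(s, t[i] + ovl, to)
    }, character(1))
    frag_tbl(win, core, win[nxt])
  } else {
    starts <- c(0L, t + ovl)
    ends <- c(t, L)
    core <- substring(s, starts + 1L, ends)
    frag_tbl(c(NA_character_, win), core, c(win, NA_character_))
  }
}

# internal: classify a fragment w.r.t. residual recognition sites.
# "recut" = a motif's cut window extends past a sticky end (the enzyme
# would re-cut any ligated junction); "flagged" = window extends past a
# blunt terminus only (harmless, the window lies outside any molecule).
residual_site_class <- function(left_end, core, right_end, enz) {
  full <- paste0(
    ifelse(is.na(left_end), "", left_end), core,
    ifelse(is.na(right_end), "", right_end)
  )
  n <- nchar(full)
  hits <- scan_sites(dna(full), enz)
  if (nrow(hits) == 0L) return("clean")
  cls <- "clean"
  le_len <- if (is.na(left_end)) 0L else nchar(left_end)
  re_len <- if (is.na(right_end)) 0L else nchar(right_end)
  ds_from <- le_len
  ds_to <- n - re_len
  for (i in seq_len(nrow(hits))) {
    if (hits$strand[i] == "+") {
      w1 <- hits$end[i] + enz$cut_offset_top
      w2 <- hits$end[i] + enz$cut_offset_bottom
    } else {
      w1 <- hits$start[i] - enz$cut_offset_bottom
      w2 <- hits$start[i] - enz$cut_offset_top
    }
    beyond_right <- w2 > ds_to
    beyond_left <- w1 < ds_from
    into_sticky <- (beyond_right && re_len > 0L) || (beyond_left && le_len > 0L)
    if (into_sticky || (!beyond_right && !beyond_left)) return("recut")
    cls <- "flagged"
  }
  cls
}

# internal: enumerate simple cycles in the right_end -> left_end match
# graph; each cycle is a fragment ordering that circularises. Cycles are
# enumerated with the smallest participating index first, so each cyclic
# order is produced once.
enumerate_cycles <- function(left, right, max_cycles = 5000L) {
  n <- length(left)
  cycles <- list()
  count <- 0L
  succ <- lapply(seq_len(n), function(i) which(right[i] == left))
  for (start in seq_len(n)) {
    stack <- list(list(path = start, used = start))
    while (length(stack)) {
      node <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      last <- node$path[length(node$path)]
      for (j in succ[[last]]) {
        if (j == start) {
          cycles[[length(cycles) + 1L]] <- node$path
          count <- count + 1L
          if (count > max_cycles) {
            abort("Ambiguous assembly: circularisation search exploded.",
                  class = c("mocloforge_error_assembly", "mocloforge_error"))
          }
        } else if (j > start && !(j %in% node$used)) {
          stack[[length(stack) + 1L]] <-
            list(path = c(node$path, j), used = c(node$used, j))
        }
      }
    }
  }
  cycles
}

#' Canonical form of a circular sequence
#'
#' The lexicographically least string over all rotations of the sequence
#' and of its reverse complement. Two circular molecules are the same iff
#' their canonical forms are equal.
#'
#' @param x A circular `dna` object (or string, taken as circular).
#' @return A character string.
#' @examples
#' canonical_circular(dna("TGCA", topology = "circular"))
#' @export
canonical_circular <- function(x) {
  s <- seq_chr(x)
  L <- nchar(s)
  best_rotation <- function(z) {
    d <- paste0(z, z)
    min(vapply(seq_len(L), function(i) substr(d, i, i + L - 1L), character(1)))
  }
  min(best_rotation(s), best_rotation(revcomp(s)))
}

#' One-pot Golden Gate assembly
#'
#' Digests every input molecule with the assembly enzyme, discards
#' fragments that still carry a recognition site oriented to re-cut a
#' ligated junction (the one-pot cut-ligate equilibrium removes them from
#' productive assemblies), and searches for circular products by matching
#' sticky ends. Assembly succeeds iff exactly one distinct circular
#' product exists that uses each retained fragment at most once, draws
#' fragments from at least two input molecules, and carries no residual
#' recognition site of the assembly enzyme. Re-ligations that merely
#' reconstitute a single input molecule are reported as diagnostics (and
#' returned as the product only when a single molecule was supplied).
#'
#' @param molecules A list of `dna` objects (named for diagnostics).
#' @param enzyme Assembly enzyme name or registry row (default BsmBI).
#' @return An `assembly_result`: list with `product` (circular `dna`),
#'   `used_fragments` (provenance labels in ligation order), and
#'   `diagnostics` (character). Failure raises a classed error
#'   (`mocloforge_error_no_assembly` or `mocloforge_error_ambiguous_assembly`).
#' @export
golden_gate <- function(molecules, enzyme = "BsmBI") {
  if (is_dna(molecules)) molecules <- list(molecules)
  if (!is.list(molecules) || length(molecules) < 1L) {
    abort("`molecules` must be a non-empty list of dna objects.",
          class = c("mocloforge_error_validation", "mocloforge_error"))
  }
  enz <- as_enzymes(enzyme)
  labels <- names(molecules) %||% rep("", length(molecules))
  labels <- ifelse(nzchar(labels), labels, paste0("mol", seq_along(molecules)))
  diagnostics <- character(0)

  frs <- dplyr::bind_rows(lapply(seq_along(molecules), function(i) {
    f <- digest(molecules[[i]], enz, label = labels[i])
    if (isTRUE(attr(f, "uncut"))) {
      diagnostics <<- c(diagnostics,
        sprintf("%s has no %s site and was left uncut.", labels[i], enz$name))
    }
    if (nrow(f)) f$molecule <- i
    f
  }))
  if (nrow(frs) == 0L) {
    abort("No assembly: no molecule was cut by the enzyme.",
          class = c("mocloforge_error_no_assembly", "mocloforge_error"),
          diagnostics = diagnostics)
  }

  frs$class <- vapply(seq_len(nrow(frs)), function(i) {
    residual_site_class(frs$left_end[i], frs$core[i], frs$right_end[i], enz)
  }, character(1))
  single_mode <- length(molecules) == 1L
  retained <- frs[!is.na(frs$left_end) & !is.na(frs$right_end) &
                    (single_mode | frs$class != "recut"), ]
  for (i in which(frs$class == "flagged")) {
    diagnostics <- c(diagnostics, sprintf(
      "%s carries an outward-pointing %s site past a blunt end.",
      frs$provenance[i], enz$name))
  }

  products <- list()
  if (nrow(retained)) {
    cycles <- enumerate_cycles(retained$left_end, retained$right_end)
    for (cyc in cycles) {
      prod <- paste0(retained$left_end[cyc], retained$core[cyc], collapse = "")
      mols <- unique(retained$molecule[cyc])
      has_site <- nrow(scan_sites(dna(prod, topology = "circular"), enz)) > 0L
      products[[length(products) + 1L]] <- list(
        seq = prod, canonical = canonical_circular(prod),
        provenance = retained$provenance[cyc],
        n_molecules = length(mols), single = mols[1],
        has_site = has_site
      )
    }
  }

  canon_of <- function(ps) vapply(ps, `[[`, character(1), "canonical")
  multi <- products[vapply(products, function(p) p$n_molecules >= 2L && !p$has_site, logical(1))]
  relig <- products[vapply(products, function(p) p$n_molecules < 2L, logical(1))]
  recut <- products[vapply(products, function(p) p$n_molecules >= 2L && p$has_site, logical(1))]
  for (p in recut) {
    diagnostics <- c(diagnostics, sprintf(
      "Discarded a candidate product retaining a %s site (would be re-cut).",
      enz$name))
  }

  input_canon <- vapply(seq_along(molecules), function(i) {
    if (dna_topology(molecules[[i]]) == "circular")
      canonical_circular(molecules[[i]]) else NA_character_
  }, character(1))
  for (p in relig) {
    if (!is.na(input_canon[p$single]) && p$canonical == input_canon[p$single]) {
      diagnostics <- c(diagnostics,
        sprintf("re-ligation: %s can reconstitute itself.", labels[p$single]))
    }
  }

  pick <- function(ps) {
    uc <- unique(canon_of(ps))
    if (length(uc) > 1L) {
      abort(paste0("Ambiguous assembly: ", length(uc),
                   " distinct circular products."),
            class = c("mocloforge_error_ambiguous_assembly", "mocloforge_error"),
            diagnostics = diagnostics, products = uc)
    }
    ps[[1]]
  }

  chosen <- NULL
  if (length(multi)) {
    chosen <- pick(multi)
  } else if (single_mode && length(relig)) {
    chosen <- pick(relig)
    diagnostics <- unique(c(diagnostics,
      sprintf("re-ligation: product reconstitutes %s.", labels[1])))
  }
  if (is.null(chosen)) {
    abort("No assembly: no circular product could be formed.",
          class = c("mocloforge_error_no_assembly", "mocloforge_error"), diagnostics = diagnostics)
  }

  structure(
    list(
      product = dna(chosen$canonical, topology = "circular"),
      used_fragments = chosen$provenance,
      diagnostics = unique(diagnostics)
    ),
    class = "assembly_result"
  )
}

#' @export
print.assembly_result <- function(x, ...) {
  cat(sprintf("<assembly_result> circular product, %d nt, from %d fragment(s)\n",
              dna_length(x$product), length(x$used_fragments)))
  if (length(x$diagnostics)) cat(paste0("  - ", x$diagnostics, "\n"), sep = "")
  invisible(x)
}

#' @export
tidy.assembly_result <- function(x, ...) {
  tibble::tibble(order = seq_along(x$used_fragments),
                 provenance = x$used_fragments)
}

#' @export
glance.assembly_result <- function(x, ...) {
  tibble::tibble(product_length = dna_length(x$product),
                 n_fragments = length(x$used_fragments),
                 n_diagnostics = length(x$diagnostics))
}

#' Linearise a plasmid at its NotI site
#'
#' Integration cassettes are released from their assembled plasmid by NotI
#' digestion. With exactly one site the single linear fragment is
#' returned; with several, all fragments are returned with a warning.
#'
#' @param plasmid A circular `dna` object containing at least one NotI site.
#' @return A fragment tibble as returned by [digest()].
#' @export
notI_linearize <- function(plasmid) {
  plasmid <- as_dna(plasmid)
  if (dna_topology(plasmid) != "circular") {
    abort("`plasmid` must be circular.", class = c("mocloforge_error_validation", "mocloforge_error"))
  }
  hits <- scan_sites(plasmid, "NotI")
  if (nrow(hits) == 0L) {
    abort("No NotI site: the plasmid cannot be linearised.",
          class = c("mocloforge_error_assembly", "mocloforge_error"))
  }
  frs <- digest(plasmid, "NotI", label = "plasmid")
  if (nrow(frs) > 1L) {
    warn(sprintf("Plasmid has %d NotI sites; returning all %d fragments.",
                 nrow(hits), nrow(frs)))
  }
  frs
}

#' Simulate an exact-match PCR
#'
#' The forward primer's binding region must occur exactly once on the
#' template top strand and the reverse primer's binding region exactly
#' once as a reverse-complement match at or downstream of it; matching is
#' exact (no mismatches modeled). The amplicon is
#' `fwd tail + template window + revcomp(rev tail)`.
#'
#' @param template A linear `dna` object or string.
#' @param fwd,rev Primers: lists or one-row data frames with elements
#'   `tail` and `binding` (tails may be empty strings).
#' @return A linear `dna` amplicon.
#' @export
simulate_pcr <- function(template, fwd, rev) {
  template <- as_dna(template)
  s <- seq_chr(template)
  p <- function(x, what) {
    x <- as.list(x)
    if (is.null(x$binding)) {
      abort(sprintf("%s primer needs a `binding` element.", what),
            class = c("mocloforge_error_validation", "mocloforge_error"))
    }
    list(tail = toupper(x$tail %||% ""), binding = toupper(as.character(x$binding)))
  }
  fwd <- p(fwd, "Forward")
  rev <- p(rev, "Reverse")
  fstarts <- fixed_starts(s, fwd$binding)
  if (length(fstarts) != 1L) {
    abort(sprintf("Forward binding region matches the template %d times (need exactly 1).",
                  length(fstarts)),
          class = c("mocloforge_error_pcr", "mocloforge_error"))
  }
  rsite <- revcomp(rev$binding)
  rstarts <- fixed_starts(s, rsite)
  if (length(rstarts) != 1L) {
    abort(sprintf("Reverse binding region matches the template %d times (need exactly 1).",
                  length(rstarts)),
          class = c("mocloforge_error_pcr", "mocloforge_error"))
  }
  if (rstarts < fstarts) {
    abort("Reverse binding site lies upstream of the forward binding site.",
          class = c("mocloforge_error_pcr", "mocloforge_error"))
  }
  rend <- rstarts + nchar(rsite) - 1L
  rc_tail <- if (nzchar(rev$tail)) revcomp(rev$tail) else ""
  dna(paste0(fwd$tail, substr(s, fstarts, rend), rc_tail))
}
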