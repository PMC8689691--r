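# Independent oracles and shared fixtures for the suite.

# Guard-compliant, mutually compatible destination-vector overhangs used
# throughout the array tests.
VEND5 <- "TTCT"
VEND3 <- "ATTG"

rand_seq <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

# Oracle 1: site scanning via Biostrings (independent of the package's
# string matching). Returns a data frame of (enzyme, start, end, strand)
# in the package's 0-based half-open convention; circular sequences are
# handled by scanning seq + prefix.
biostrings_scan <- function(seq, registry, circular = FALSE) {
  rows <- list()
  L <- nchar(seq)
  for (i in seq_len(nrow(registry))) {
    motif <- registry$recognition[i]
    mlen <- nchar(motif)
    subject <- if (circular) paste0(seq, substr(seq, 1, mlen - 1)) else seq
    subj <- Biostrings::DNAString(subject)
    plus <- Biostrings::start(Biostrings::matchPattern(motif, subj))
    rcm <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(motif)))
    minus <- if (motif == rcm) integer(0) else
      Biostrings::start(Biostrings::matchPattern(rcm, subj))
    plus <- plus[plus <= L]
    minus <- minus[minus <= L]
    if (length(plus) || length(minus)) {
      rows[[length(rows) + 1L]] <- data.frame(
        enzyme = registry$name[i],
        start = c(plus, minus) - 1L,
        end = c(plus, minus) - 1L + mlen,
        strand = rep(c("+", "-"), c(length(plus), length(minus)))
      )
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(enzyme = character(0), start = integer(0),
                      end = integer(0), strand = character(0))
  }
  out[order(out$enzyme, out$start, out$strand), , drop = FALSE]
}

# Oracle 2: positional match count by explicit character loop.
naive_matches <- function(a, b) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  sum(av == bv)
}

naive_conflict <- function(a, b, threshold = 3) {
  naive_matches(a, b) >= threshold ||
    naive_matches(a, revcomp(b)) >= threshold
}

# Brute-force conflict audit of a design's junction set: enumerates all
# unordered junction pairs plus each junction against its own reverse
# complement.
audit_junctions <- function(junctions, threshold = 3) {
  n <- length(junctions)
  conflicts <- 0L
  for (i in seq_len(n)) {
    if (naive_matches(junctions[i], revcomp(junctions[i])) >= threshold) {
      conflicts <- conflicts + 1L
    }
    for (j in seq_len(n)) {
      if (j > i && naive_conflict(junctions[i], junctions[j], threshold)) {
        conflicts <- conflicts + 1L
      }
    }
  }
  conflicts
}

# Oracle 3: exhaustive one-pot assembly. Digests with the package's
# digest(), then enumerates every ordering of every subset of sticky
# fragments and collects all circular chains; canonicalisation is done
# independently (sorted rotations of both strands).
oracle_canonical <- function(s) {
  L <- nchar(s)
  rots <- function(z) {
    d <- paste0(z, z)
    sapply(seq_len(L), function(i) substr(d, i, i + L - 1))
  }
  sort(c(rots(s), rots(revcomp(s))))[1]
}

oracle_products <- function(fragments) {
  keep <- !is.na(fragments$left_end) & !is.na(fragments$right_end)
  fr <- fragments[keep, , drop = FALSE]
  mol <- sub(":frag[0-9]+$", "", fr$provenance)
  n <- nrow(fr)
  found <- character(0)
  recurse <- function(path, used) {
    last <- path[length(path)]
    # close the cycle? (products must draw on >= 2 input molecules)
    if (fr$right_end[last] == fr$left_end[path[1]] &&
        length(unique(mol[path])) >= 2) {
      prod <- paste0(fr$left_end[path], fr$core[path], collapse = "")
      found <<- c(found, oracle_canonical(prod))
    }
    for (j in seq_len(n)) {
      if (!used[j] && fr$right_end[last] == fr$left_end[j]) {
        used[j] <- TRUE
        recurse(c(path, j), used)
        used[j] <- FALSE
      }
    }
  }
  for (i in seq_len(n)) {
    used <- rep(FALSE, n)
    used[i] <- TRUE
    recurse(i, used)
  }
  unique(found)
}

# Build a small random Golden Gate instance: a target circle cut into
# `k` parts with chosen overhangs, each part wrapped into a linear
# amplicon with outward-discarding BsmBI sites, plus a backbone vector.
# Returns the molecules and the expected insert arcs.
make_gg_instance <- function(k, overhangs, core_len = 12) {
  stopifnot(length(overhangs) == k + 1)
  prefix <- "AACGTCTCA"
  suffix <- "TGAGACGTT"
  cores <- replicate(k, {
    repeat {
      s <- rand_seq(core_len)
      if (nrow(scan_sites(dna(s), "BsmBI")) == 0 &&
          mocloforge:::guard_left_ok(s) && mocloforge:::guard_right_ok(s)) break
    }
    s
  })
  amplicons <- lapply(seq_len(k), function(i) {
    dna(paste0(prefix, overhangs[i], cores[i], overhangs[i + 1], suffix))
  })
  names(amplicons) <- paste0("amp", seq_len(k))
  amplicons
}
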