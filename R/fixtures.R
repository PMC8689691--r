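# Seeded synthetic-sequence generators. Each generator draws from its own
# deterministic stream (derived from the config seed and a stream name),
# so adding one fixture never perturbs another's output, and applies
# rejection sampling so no generated sequence carries a registry
# recognition motif except those intentionally placed.
#
# Junction guards: sequences destined to sit next to free sequence in an
# amplicon or assembled product additionally reject termini that form a
# proper prefix/suffix of a BsmBI motif (either strand). Without the
# guard, a BsmBI site can arise by chance across a designed junction
# (tail|template, insert|backbone, ...) at a rate of a fraction of a
# percent per junction, and such a product is correctly rejected by the
# simulator because the enzyme would re-cut it. The guard makes fixture
# geometry independent of such coincidences.

#' Fixture generator configuration
#'
#' @param seed Integer seed; all fixture output is a pure function of the
#'   config and arguments.
#' @param spacer_len Spacer length in nt (default 20, the targeting
#'   portion of a gRNA).
#' @param separator_len Length of the gRNA-separating sequence (default
#'   28, the length of a Csy4 recognition sequence).
#' @param scaffold_len Length of the placeholder gRNA scaffold
#'   (default 76).
#' @param backbone_len Length of the placeholder vector backbone
#'   (default 300).
#' @return A `fixture_config` list.
#' @export
fixture_config <- function(seed = 1L, spacer_len = 20L, separator_len = 28L,
                           scaffold_len = 76L, backbone_len = 300L) {
  lens <- c(spacer_len, separator_len, scaffold_len, backbone_len)
  if (any(lens < 4L)) {
    abort("All fixture lengths must be >= 4 nt.",
          class = c("mocloforge_error_validation", "mocloforge_error"))
  }
  structure(list(seed = as.integer(seed), spacer_len = as.integer(spacer_len),
                 separator_len = as.integer(separator_len),
                 scaffold_len = as.integer(scaffold_len),
                 backbone_len = as.integer(backbone_len)),
            class = "fixture_config")
}

# internal: derived seed for a named stream, kept below 2^31
stream_seed <- function(seed, name) {
  codes <- utf8ToInt(name)
  h <- sum(codes * seq_along(codes)) %% 65011L
  as.integer((abs(seed) %% 32003L) * 65011L + h)
}

# internal: evaluate expr under a named RNG stream, restoring global state
with_stream <- function(seed, name, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(stream_seed(seed, name))
  force(expr)
}

rand_bases <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

# internal: TRUE when no registry motif occurs on either strand
motif_free <- function(s, enzymes = enzyme_registry()) {
  nrow(scan_sites(dna(s), enzymes)) == 0L
}

bsmbi_parts <- function() {
  m <- c("CGTCTC", "GAGACG")
  list(
    prefixes = unique(unlist(lapply(m, function(x)
      vapply(1:5, function(k) substr(x, 1, k), character(1))))),
    suffixes = unique(unlist(lapply(m, function(x)
      vapply(1:5, function(k) substr(x, 7 - k, 6), character(1)))))
  )
}

# guard_left: no prefix of s completes a BsmBI motif begun in whatever
# precedes it; guard_right: symmetric for whatever follows.
guard_left_ok <- function(s) {
  suf <- bsmbi_parts()$suffixes
  !any(vapply(suf, function(x) startsWith(s, x), logical(1)))
}
guard_right_ok <- function(s) {
  pre <- bsmbi_parts()$prefixes
  !any(vapply(pre, function(x) endsWith(s, x), logical(1)))
}

# internal: rejection-sample one sequence free of the given motifs
draw_free <- function(len, check = function(s) TRUE,
                      enzymes = enzyme_registry(), max_tries = 10000L) {
  for (i in seq_len(max_tries)) {
    s <- rand_bases(len)
    if (motif_free(s, enzymes) && check(s)) return(s)
  }
  abort("Rejection sampling failed to produce a motif-free sequence.",
        class = c("mocloforge_error_internal", "mocloforge_error"))
}

# enzymes whose sites always block Golden Gate / integration use
blocking_enzymes <- function() {
  reg <- enzyme_registry()
  reg[reg$name %in% c("BsaI", "BsmBI", "NotI"), ]
}

#' Random motif-free gRNA spacers
#'
#' @param n Number of spacers (1 to 1000).
#' @param cfg A [fixture_config()].
#' @return A character vector of `n` spacers of `cfg$spacer_len` nt, each
#'   free of every registry recognition motif; byte-identical across runs
#'   for the same config.
#' @export
random_spacers <- function(n, cfg = fixture_config()) {
  if (n < 1L || n > 1000L) {
    abort("`n` must be between 1 and 1000.",
          class = c("mocloforge_error_validation", "mocloforge_error"))
  }
  with_stream(cfg$seed, "spacers", {
    vapply(seq_len(n), function(i) draw_free(cfg$spacer_len), character(1))
  })
}

#' Random domestication-ready part sequence
#'
#' A stand-in coding/part sequence for exercising the domestication
#' designer: free of the blocking motifs (BsaI, BsmBI, NotI — legacy
#' BioBrick/BglBrick sites may occur, as in real parts) and
#' junction-guarded at both termini so that adjoining it to fusion sites
#' cannot create a BsmBI site by chance.
#'
#' @param len Part length in nt (>= 6).
#' @param cfg A [fixture_config()].
#' @param stream Stream name, so multiple independent parts can be drawn
#'   from one config.
#' @return A character string of length `len`.
#' @export
random_part <- function(len, cfg = fixture_config(), stream = "part") {
  if (len < 6L) {
    abort("`len` must be >= 6.", class = c("mocloforge_error_validation", "mocloforge_error"))
  }
  with_stream(cfg$seed, paste0("part:", stream), {
    draw_free(len, function(s) guard_left_ok(s) && guard_right_ok(s),
              enzymes = blocking_enzymes())
  })
}

#' Synthetic MoClo-style entry/destination vector
#'
#' A circular molecule modelling the universal cloning-vector
#' architecture: a motif-free backbone plus a dropout cassette flanked by
#' two inward-facing BsmBI sites whose cut windows expose `fusion5` (5')
#' and `fusion3` (3'). The recognition motifs sit inside the dropout, so
#' they leave with it during assembly and the product is BsmBI-free.
#' BsmBI digestion yields exactly two fragments: the dropout (ends
#' `fusion5`/`fusion3`) and the backbone (ends `fusion3`/`fusion5`).
#'
#' @param cfg A [fixture_config()].
#' @param fusion5,fusion3 The two 4-nt overhangs to expose. Must differ
#'   and must not conflict at threshold 3.
#' @return A circular `dna`.
#' @export
make_entry_vector <- function(cfg = fixture_config(), fusion5, fusion3) {
  fusion5 <- toupper(fusion5); fusion3 <- toupper(fusion3)
  if (nchar(fusion5) != 4L || nchar(fusion3) != 4L) {
    abort("Fusion sites must be 4 nt.", class = c("mocloforge_error_validation", "mocloforge_error"))
  }
  if (fusion5 == fusion3 || ends_conflict(fusion5, fusion3, 3L)) {
    abort("Fusion sites are identical or conflicting; the dropout junctions would scramble.",
          class = c("mocloforge_error_validation", "mocloforge_error"))
  }
  dropout_core_len <- 40L
  with_stream(cfg$seed, paste0("entry:", fusion5, fusion3), {
    for (i in seq_len(1000L)) {
      backbone <- draw_free(cfg$backbone_len,
                            function(s) guard_left_ok(s) && guard_right_ok(s))
      core <- draw_free(dropout_core_len)
      vec <- paste0(fusion5, "A", "GAGACG", core, "CGTCTC", "A", fusion3,
                    backbone)
      mol <- dna(vec, topology = "circular")
      bsmbi <- scan_sites(mol, "BsmBI")
      other <- scan_sites(mol, c("BsaI", "NotI"))
      if (nrow(bsmbi) == 2L && nrow(other) == 0L) return(mol)
    }
    abort("Could not place a clean entry vector.",
          class = c("mocloforge_error_internal", "mocloforge_error"))
  })
}

#' Synthetic scaffold + separator PCR template
#'
#' A linear template modelling a scaffold-gRNA sequence followed by a
#' gRNA-separating sequence (by default 28 nt, the length of a Csy4
#' recognition sequence). Both portions are random placeholders of the
#' correct lengths, motif-free and junction-guarded; real use accepts a
#' user-supplied template FASTA.
#'
#' @param cfg A [fixture_config()].
#' @return A list with `template` (linear `dna`), `scaffold`,
#'   `separator`, and the canonical binding parts `binding_fwd` (first 18
#'   nt of the scaffold) and `binding_rev` (reverse complement of the
#'   last 18 nt of the separator).
#' @export
make_template <- function(cfg = fixture_config()) {
  with_stream(cfg$seed, "template", {
    for (i in seq_len(1000L)) {
      scaffold <- draw_free(cfg$scaffold_len, guard_left_ok)
      separator <- draw_free(cfg$separator_len, guard_right_ok)
      tmpl <- paste0(scaffold, separator)
      if (motif_free(tmpl)) {
        return(list(
          template = dna(tmpl),
          scaffold = scaffold,
          separator = separator,
          binding_fwd = substr(scaffold, 1L, 18L),
          binding_rev = revcomp(substr(separator, cfg$separator_len - 17L,
                                       cfg$separator_len))
        ))
      }
    }
    abort("Could not draw a clean template.",
          class = c("mocloforge_error_internal", "mocloforge_error"))
  })
}
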