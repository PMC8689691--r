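# Level-0 part domestication: type-specific BsmBI primer tails, forbidden
# site reporting, and simulated entry-vector assembly.

#' MoClo part-type fusion sites
#'
#' The fusion-site table of the yeast MoClo standard, shipped as an
#' editable tab-separated file (`inst/extdata/part_types.tsv`). Adjacent
#' standard types share a junction (the 3' fusion site of type k equals
#' the 5' fusion site of type k + 1), so non-standard parts spanning
#' several types are expressed by choosing prefix and suffix types
#' independently. The type-2/type-3 junction is `TATG`, placing the start
#' codon inside the overhang.
#'
#' @param path Optional alternative table with columns `type`,
#'   `fusion_site_5`, `fusion_site_3`.
#' @return A tibble with columns `type`, `fusion_site_5`, `fusion_site_3`.
#' @export
part_type_table <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "part_types.tsv", package = "mocloforge")
  }
  tbl <- utils::read.delim(path, sep = "\t", colClasses = "character")
  tibble::as_tibble(tbl)
}

# internal: fusion sites for one part-type label
part_type <- function(label, table = part_type_table()) {
  hit <- table[table$type == as.character(label), ]
  if (nrow(hit) != 1L) {
    abort(sprintf("Unknown part type '%s' (known: %s).",
                  label, paste(table$type, collapse = ", ")),
          class = c("mocloforge_error_validation", "mocloforge_error"))
  }
  list(fusion5 = hit$fusion_site_5, fusion3 = hit$fusion_site_3)
}

COMPAT_CATEGORIES <- list(
  moclo = c("BsaI", "BsmBI"),
  biobrick = c("EcoRI", "XbaI", "SpeI", "PstI"),
  bglbrick = c("BglII", "BamHI", "EcoRI", "XhoI"),
  integration = "NotI"
)

#' Report recognition sites that interfere with assembly standards
#'
#' Scans a part for sites that interfere with MoClo (BsaI, BsmBI),
#' BioBrick (EcoRI, XbaI, SpeI, PstI) or BglBrick (BglII, BamHI, EcoRI,
#' XhoI) compatibility, or with use in integration cassettes (NotI).
#' EcoRI hits appear in both the BioBrick and BglBrick categories. MoClo
#' and integration sites must always be removed from a part, so they set
#' the `blocking` flag; legacy-standard sites are warnings only, since
#' that compatibility is not always required.
#'
#' @param part_seq Linear `dna` object or DNA string.
#' @return A `compat_report`: list with `hits` (tibble `category`,
#'   `enzyme`, `start`, `end`, `strand`) and `blocking` (logical).
#' @examples
#' compatibility_report("CCAGATCTGG")  # BglBrick hit, not blocking
#' @export
compatibility_report <- function(part_seq) {
  part_seq <- as_dna(part_seq)
  hits <- dplyr::bind_rows(lapply(names(COMPAT_CATEGORIES), function(cat) {
    h <- scan_sites(part_seq, COMPAT_CATEGORIES[[cat]])
    if (nrow(h)) h$category <- cat
    h
  }))
  if (nrow(hits)) {
    hits <- hits[, c("category", "enzyme", "start", "end", "strand")]
  } else {
    hits <- tibble::tibble(category = character(0), enzyme = character(0),
                           start = integer(0), end = integer(0),
                           strand = character(0))
  }
  structure(
    list(hits = hits,
         blocking = any(hits$category %in% c("moclo", "integration"))),
    class = "compat_report"
  )
}

#' @export
print.compat_report <- function(x, ...) {
  cat(sprintf("<compat_report> %d interfering site(s); blocking: %s\n",
              nrow(x$hits), x$blocking))
  if (nrow(x$hits)) print(x$hits)
  invisible(x)
}

#' @export
tidy.compat_report <- function(x, ...) x$hits

#' @export
glance.compat_report <- function(x, ...) {
  counts <- lapply(names(COMPAT_CATEGORIES), function(cat) {
    sum(x$hits$category == cat)
  })
  names(counts) <- names(COMPAT_CATEGORIES)
  tibble::as_tibble(c(counts, list(blocking = x$blocking)))
}

#' Design type-specific domestication primers for a level-0 part
#'
#' Generates one forward and one reverse primer candidate per binding
#' length in `[min_binding, max_binding]`. Each candidate's tail is
#' `flank + BsmBI recognition (CGTCTC) + 1-nt spacer + fusion site`, so
#' that BsmBI digestion of the amplicon exposes exactly the type-specific
#' fusion sites: forward candidates use the 5' fusion site of
#' `prefix_type`, reverse candidates the reverse complement of the 3'
#' fusion site of `suffix_type`. Candidates carry length, GC fraction and
#' Wallace Tm (binding region only) and are sorted by `|tm - target_tm|`,
#' then by length. Interfering internal sites are reported, not refused:
#' a part with internal BsaI/BsmBI/NotI sites still gets candidates, but
#' the report blocks downstream [simulate_level0()].
#'
#' @param part_seq Linear `dna` object or string; the raw part.
#' @param prefix_type,suffix_type Part-type labels from
#'   [part_type_table()] (may differ, for multi-type spanning parts).
#' @param min_binding,max_binding Binding-region length range (default
#'   18-30 nt).
#' @param target_tm Wallace Tm aimed for when ranking candidates
#'   (default 60).
#' @param flank,spacer_base Tail bases around the BsmBI site.
#' @param type_table Fusion-site table (default shipped table).
#' @return A `part_primer_design`: list with `forward` and `reverse`
#'   candidate tibbles, `report` (a `compat_report`), and the fusion
#'   sites used.
#' @export
design_part_primers <- function(part_seq, prefix_type, suffix_type,
                                min_binding = 18L, max_binding = 30L,
                                target_tm = 60, flank = TAIL_FLANK,
                                spacer_base = TAIL_SPACER,
                                type_table = part_type_table()) {
  part_seq <- as_dna(part_seq)
  s <- seq_chr(part_seq)
  n <- nchar(s)
  pre <- part_type(prefix_type, type_table)
  suf <- part_type(suffix_type, type_table)
  if (n < min_binding) {
    abort(sprintf("Part (%d nt) is shorter than min_binding (%d nt).",
                  n, min_binding),
          class = c("mocloforge_error_validation", "mocloforge_error"))
  }
  max_binding <- min(max_binding, n)
  prefix <- tail_prefix(flank, spacer_base)

  candidates <- function(orientation) {
    lens <- seq.int(min_binding, max_binding)
    rows <- lapply(lens, function(L) {
      if (orientation == "forward") {
        binding <- substr(s, 1L, L)
        tail <- paste0(prefix, pre$fusion5)
      } else {
        binding <- revcomp(substr(s, n - L + 1L, n))
        tail <- paste0(prefix, revcomp(suf$fusion3))
      }
      tibble::tibble(
        orientation = orientation,
        binding_length = L,
        sequence = paste0(tail, binding),
        tail = tail,
        binding = binding,
        length = nchar(tail) + L,
        gc = gc_fraction(binding),
        tm = wallace_tm(binding)
      )
    })
    out <- dplyr::bind_rows(rows)
    out[order(abs(out$tm - target_tm), out$length), ]
  }

  report <- compatibility_report(part_seq)
  if (report$blocking) {
    warn(paste("Part contains BsaI/BsmBI/NotI recognition site(s);",
               "these must be removed before level-0 assembly."))
  }
  structure(
    list(forward = candidates("forward"), reverse = candidates("reverse"),
         report = report,
         prefix_type = as.character(prefix_type),
         suffix_type = as.character(suffix_type),
         fusion5 = pre$fusion5, fusion3 = suf$fusion3,
         target_tm = target_tm),
    class = "part_primer_design"
  )
}

#' @export
print.part_primer_design <- function(x, ...) {
  cat(sprintf(
    "<part_primer_design> types %s|%s (fusion sites %s/%s), %d + %d candidates\n",
    x$prefix_type, x$suffix_type, x$fusion5, x$fusion3,
    nrow(x$forward), nrow(x$reverse)))
  if (x$report$blocking) cat("  blocking sites present - see $report\n")
  invisible(x)
}

#' @export
tidy.part_primer_design <- function(x, ...) {
  dplyr::bind_rows(x$forward, x$reverse)
}

#' @export
glance.part_primer_design <- function(x, ...) {
  tibble::tibble(
    prefix_type = x$prefix_type, suffix_type = x$suffix_type,
    fusion5 = x$fusion5, fusion3 = x$fusion3,
    n_forward = nrow(x$forward), n_reverse = nrow(x$reverse),
    n_interfering_sites = nrow(x$report$hits),
    blocking = x$report$blocking
  )
}

#' Plot primer candidates by Tm and binding length
#'
#' @param object A `part_primer_design`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.part_primer_design <- function(object, ...) {
  ggplot2::ggplot(tidy(object),
                  ggplot2::aes(x = .data$binding_length, y = .data$tm,
                               colour = .data$orientation)) +
    ggplot2::geom_hline(yintercept = object$target_tm, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::geom_point() +
    ggplot2::labs(x = "binding length (nt)", y = "Wallace Tm (°C)",
                  title = "Domestication primer candidates")
}

#' Simulate the level-0 Golden Gate assembly of a domesticated part
#'
#' Simulates PCR of the part with one chosen forward and one chosen
#' reverse candidate, then the BsmBI Golden Gate reaction with the entry
#' vector, and returns the unique circular level-0 product. The part must
#' be free of internal BsaI/BsmBI/NotI sites (blocking sites are refused
#' with an explanatory error); the product contains no BsmBI site and its
#' insert equals `fusion5 + part + fusion3`. A part whose 5' fusion site
#' is `TATG` and which itself begins with `ATG` keeps its own start codon
#' and triggers a duplicated-start-codon warning (nothing is trimmed
#' silently).
#'
#' @inheritParams design_part_primers
#' @param entry_vector Circular entry vector with two BsmBI sites cutting
#'   around a dropout whose flanking overhangs equal the chosen fusion
#'   sites (see [make_entry_vector()]).
#' @param fwd,rev One forward and one reverse candidate row from
#'   [design_part_primers()] for the same types.
#' @return The circular level-0 `dna` product, with the assembly result
#'   in attribute `"assembly"`.
#' @export
simulate_level0 <- function(part_seq, prefix_type, suffix_type,
                            entry_vector, fwd, rev,
                            type_table = part_type_table()) {
  part_seq <- as_dna(part_seq)
  s <- seq_chr(part_seq)
  pre <- part_type(prefix_type, type_table)
  suf <- part_type(suffix_type, type_table)
  report <- compatibility_report(part_seq)
  if (report$blocking) {
    blocked <- unique(report$hits$enzyme[report$hits$category %in%
                                           c("moclo", "integration")])
    abort(sprintf(
      paste("Part contains internal %s recognition site(s); these always",
            "interfere with Golden Gate assembly and must be removed",
            "before domestication."),
      paste(blocked, collapse = ", ")),
      class = c("mocloforge_error_blocking", "mocloforge_error"), report = report)
  }
  if (pre$fusion5 == "TATG" && startsWith(s, "ATG")) {
    warn(paste("The TATG fusion site supplies a start codon and the part",
               "itself begins with ATG; the part's ATG is retained",
               "(possible duplicated start codon)."))
  }
  amplicon <- simulate_pcr(part_seq, fwd, rev)
  res <- golden_gate(list(amplicon = amplicon,
                          entry = as_dna(entry_vector, "circular")),
                     enzyme = "BsmBI")
  insert <- extract_insert(res$product, entry_vector, pre$fusion5, suf$fusion3)
  expected <- s
  if (insert != expected) {
    d <- first_difference(insert, expected)
    abort(sprintf(
      "Level-0 insert differs from the part at position %d (lengths %d vs %d).",
      d, nchar(insert), nchar(expected)),
      class = c("mocloforge_error_verification", "mocloforge_error"))
  }
  out <- res$product
  attr(out, "assembly") <- res
  out
}
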