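# FASTA and tabular output. Circular topology is recorded as
# "[topology=circular]" in the FASTA description (no standard field
# exists for it); sequences are wrapped at 60 columns.

#' Read a FASTA file
#'
#' Strict DNA FASTA reader: headers are preserved verbatim, lowercase
#' bases are uppercased with a warning, and any character outside
#' `ACGTacgt` (or a missing leading header) is a parse error naming the
#' offending line. A `[topology=circular]` tag in the description sets
#' the record's topology.
#'
#' @param path Path to a FASTA file.
#' @return A tibble with columns `name` (full header text after `>`),
#'   `sequence`, `topology`.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("No such file: %s", path), class = c("mocloforge_error_io", "mocloforge_error"))
  }
  lines <- readLines(path, warn = FALSE)
  headers <- integer(0)
  name <- character(0)
  seqs <- list()
  current <- NULL
  lowercase_seen <- FALSE
  for (i in seq_along(lines)) {
    line <- trimws(lines[i])
    if (!nzchar(line)) next
    if (startsWith(line, ">")) {
      current <- length(name) + 1L
      name[current] <- sub("^>", "", line)
      seqs[[current]] <- character(0)
    } else {
      if (is.null(current)) {
        abort(sprintf("FASTA parse error at line %d: sequence before any '>' header.", i),
              class = c("mocloforge_error_io", "mocloforge_error"))
      }
      if (grepl("[^ACGTacgt]", line)) {
        abort(sprintf("FASTA parse error at line %d: illegal character in sequence.", i),
              class = c("mocloforge_error_io", "mocloforge_error"))
      }
      if (grepl("[acgt]", line)) lowercase_seen <- TRUE
      seqs[[current]] <- c(seqs[[current]], toupper(line))
    }
  }
  if (!length(name)) {
    abort("FASTA parse error: file contains no records.",
          class = c("mocloforge_error_io", "mocloforge_error"))
  }
  if (lowercase_seen) {
    warn("Lowercase bases were uppercased on ingestion.")
  }
  sequence <- vapply(seqs, paste, character(1), collapse = "")
  if (any(!nzchar(sequence))) {
    abort(sprintf("FASTA parse error: record '%s' has no sequence.",
                  name[which(!nzchar(sequence))[1]]),
          class = c("mocloforge_error_io", "mocloforge_error"))
  }
  tibble::tibble(
    name = name,
    sequence = sequence,
    topology = ifelse(grepl("[topology=circular]", name, fixed = TRUE),
                      "circular", "linear")
  )
}

#' Write sequences to a FASTA file
#'
#' @param records A tibble/data frame with columns `name` and `sequence`
#'   (optional `topology`), or a named list of `dna` objects.
#' @param path Output path.
#' @param width Line-wrap width (default 60).
#' @return `path`, invisibly. `read_fasta(write_fasta(x))` round-trips
#'   ids and sequences exactly (up to line wrapping).
#' @export
write_fasta <- function(records, path, width = 60L) {
  if (is.list(records) && !is.data.frame(records)) {
    records <- tibble::tibble(
      name = names(records) %||% paste0("seq", seq_along(records)),
      sequence = vapply(records, seq_chr, character(1)),
      topology = vapply(records, dna_topology, character(1))
    )
  }
  if (!nrow(records)) {
    abort("No records to write.", class = c("mocloforge_error_io", "mocloforge_error"))
  }
  if (!"topology" %in% names(records)) records$topology <- "linear"
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (i in seq_len(nrow(records))) {
    header <- records$name[i]
    if (records$topology[i] == "circular" &&
        !grepl("[topology=circular]", header, fixed = TRUE)) {
      header <- paste(header, "[topology=circular]")
    }
    writeLines(paste0(">", header), con)
    s <- records$sequence[i]
    starts <- seq.int(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Write the primer table of a design as TSV
#'
#' One row per primer with columns `name`, `fragment_index`,
#' `orientation`, `sequence`, `tail`, `binding`, `length`, `gc`, `tm`,
#' ordered by fragment then orientation; byte-identical across runs for
#' the same design.
#'
#' @param design An `array_design` or `part_primer_design`.
#' @param path Output path.
#' @return The written tibble, invisibly.
#' @export
write_primer_table <- function(design, path) {
  tbl <- tidy(design)
  if (inherits(design, "part_primer_design")) {
    tbl$fragment_index <- 1L
    tbl$name <- sprintf("%s_bind%d", substr(tbl$orientation, 1, 1),
                        tbl$binding_length)
  } else {
    tbl$fragment_index <- tbl$fragment
  }
  tbl <- tbl[order(tbl$fragment_index, tbl$orientation), ]
  out <- tbl[, c("name", "fragment_index", "orientation", "sequence",
                 "tail", "binding", "length", "gc", "tm")]
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(tibble::as_tibble(out))
}

#' Write a machine-readable design record
#'
#' JSON record of a design's inputs and outputs, enabling exact replay.
#'
#' @param design An `array_design`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_design_record <- function(design, path) {
  stopifnot(inherits(design, "array_design"))
  rec <- list(
    spec = design$spec[c("spacers", "vector_end_5", "vector_end_3",
                         "binding_fwd", "binding_rev", "conflict_threshold",
                         "spacer_len")],
    splits = design$splits,
    junctions = design$junctions,
    primers = design$primers
  )
  jsonlite::write_json(rec, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
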