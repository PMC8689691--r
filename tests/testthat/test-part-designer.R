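test_that("the part-type table is junction-consistent with TATG at type 2|3", {
  tbl <- part_type_table()
  expect_setequal(tbl$type, c("1", "2", "3", "3a", "3b", "4", "4a", "4b",
                              "5", "6", "7", "8", "8a", "8b"))
  expect_true(all(nchar(tbl$fusion_site_5) == 4))
  expect_true(all(nchar(tbl$fusion_site_3) == 4))
  site <- function(type, which) tbl[tbl$type == type, ][[which]]
  # adjacent standard types share a junction (cyclically, 8 back to 1)
  std <- c("1", "2", "3", "4", "5", "6", "7", "8")
  for (i in seq_along(std)) {
    nxt <- std[if (i == length(std)) 1 else i + 1]
    expect_equal(site(std[i], "fusion_site_3"), site(nxt, "fusion_site_5"))
  }
  # subtype series span their parent type
  expect_equal(site("3a", "fusion_site_5"), site("3", "fusion_site_5"))
  expect_equal(site("3a", "fusion_site_3"), site("3b", "fusion_site_5"))
  expect_equal(site("3b", "fusion_site_3"), site("3", "fusion_site_3"))
  expect_equal(site("2", "fusion_site_3"), "TATG")
  expect_equal(site("3", "fusion_site_5"), "TATG")
})

test_that("compatibility reporting categorises sites and flags blockers", {
  r <- compatibility_report(paste0("CC", "AGATCT", "GG"))  # BglII only
  expect_equal(unique(r$hits$category), "bglbrick")
  expect_false(r$blocking)

  r <- compatibility_report(paste0("AA", "GGTCTC", "TT"))  # BsaI
  expect_true("moclo" %in% r$hits$category)
  expect_true(r$blocking)

  r <- compatibility_report("ACACACACAC")
  expect_equal(nrow(r$hits), 0L)
  expect_false(r$blocking)

  # EcoRI belongs to both legacy standards; NotI blocks
  r <- compatibility_report(paste0("AA", "GAATTC", "TT", "GCGGCCGC"))
  expect_setequal(r$hits$category[r$hits$enzyme == "EcoRI"],
                  c("biobrick", "bglbrick"))
  expect_true("integration" %in% r$hits$category)
  expect_true(r$blocking)
})

test_that("primer candidates carry type-specific tails and cover the length range", {
  cfg <- fixture_config(seed = 17)
  part <- random_part(80, cfg)
  d <- design_part_primers(part, "3", "3")
  # forward tails end in TATG immediately before the binding region
  expect_true(all(endsWith(d$forward$tail, "TATG")))
  expect_true(all(startsWith(d$forward$sequence,
                             paste0("AA", "CGTCTC", "A", "TATG"))))
  # reverse tails end in the reverse complement of ATCC
  expect_true(all(endsWith(d$reverse$tail, revcomp("ATCC"))))
  # one candidate per binding length per orientation
  expect_setequal(d$forward$binding_length, 18:30)
  expect_setequal(d$reverse$binding_length, 18:30)
  # bindings are verbatim substrings (or rc of substrings) of the part
  for (b in d$forward$binding) expect_true(grepl(b, part, fixed = TRUE))
  for (b in d$reverse$binding) expect_true(grepl(revcomp(b), part, fixed = TRUE))
  # candidates sorted by |tm - target|, then length
  dev <- abs(d$forward$tm - 60)
  expect_true(all(diff(dev) >= 0))
  # full sequence == tail + binding
  expect_equal(d$forward$sequence, paste0(d$forward$tail, d$forward$binding))
  expect_error(design_part_primers(part, "99", "3"),
               class = "mocloforge_error_validation")
  expect_error(design_part_primers("ATGCATGC", "3", "3"),
               class = "mocloforge_error_validation")
})

test_that("an all-A/T binding start gives the Wallace 40-degree candidate", {
  part <- paste0(strrep("AT", 10), "GGCCGGCCGGCATCATCGAT")
  d <- design_part_primers(part, "3", "4", min_binding = 20, max_binding = 24)
  shortest <- d$forward[d$forward$binding_length == 20, ]
  expect_equal(shortest$tm, 40)
  expect_equal(shortest$gc, 0)
})

test_that("interfering sites warn at design time but block simulation", {
  cfg <- fixture_config(seed = 18)
  bad <- paste0(substr(random_part(60, cfg), 1, 30), "CGTCTC",
                substr(random_part(60, cfg), 37, 60))
  expect_warning(d <- design_part_primers(bad, "3", "3"), "must be removed")
  expect_gt(nrow(d$forward), 0L)  # candidates still returned
  expect_true(d$report$blocking)
  entry <- make_entry_vector(cfg, "TATG", "ATCC")
  expect_error(
    suppressWarnings(simulate_level0(bad, "3", "3", entry,
                                     d$forward[1, ], d$reverse[1, ])),
    class = "mocloforge_error_blocking")
})

test_that("level-0 simulation returns the entry backbone carrying the part", {
  cfg <- fixture_config(seed = 19)
  part <- random_part(60, cfg)
  d <- design_part_primers(part, "3", "3")
  entry <- make_entry_vector(cfg, d$fusion5, d$fusion3)
  prod <- simulate_level0(part, "3", "3", entry, d$forward[1, ], d$reverse[1, ])
  expect_equal(dna_length(prod), 300L + 60L + 8L)
  expect_equal(nrow(scan_sites(prod, "BsmBI")), 0L)
  # the insert arc between the backbone junctions is exactly the part
  doubled <- paste0(unclass(prod), unclass(prod))
  expect_true(grepl(paste0(d$fusion5, part, d$fusion3), doubled, fixed = TRUE) ||
                grepl(revcomp(paste0(d$fusion5, part, d$fusion3)), doubled,
                      fixed = TRUE))
})

test_that("a TATG-prefixed part starting with ATG warns about the doubled start codon", {
  cfg <- fixture_config(seed = 23)
  part <- paste0("ATG", substr(random_part(63, cfg), 4, 63))
  # guard the 5' end manually: ATG... cannot complete a BsmBI motif
  d <- suppressWarnings(design_part_primers(part, "3", "3"))
  entry <- make_entry_vector(cfg, "TATG", "ATCC")
  expect_warning(
    prod <- simulate_level0(part, "3", "3", entry, d$forward[1, ], d$reverse[1, ]),
    "start codon")
  doubled <- paste0(unclass(prod), unclass(prod))
  expect_true(grepl("TATGATG", doubled, fixed = TRUE) ||
                grepl(revcomp("TATGATG"), doubled, fixed = TRUE))
})

test_that("round-trip holds across part lengths and compatible type pairs", {
  tbl <- part_type_table()
  cfg <- fixture_config(seed = 29)
  pairs <- expand.grid(prefix = tbl$type, suffix = tbl$type,
                       stringsAsFactors = FALSE)
  ok <- vapply(seq_len(nrow(pairs)), function(i) {
    f5 <- tbl$fusion_site_5[tbl$type == pairs$prefix[i]]
    f3 <- tbl$fusion_site_3[tbl$type == pairs$suffix[i]]
    f5 != f3 && !ends_conflict(f5, f3, 3)
  }, logical(1))
  pairs <- pairs[ok, ]
  set.seed(83)
  idx <- sample(nrow(pairs), 25)
  for (i in idx) {
    len <- sample(c(30, 60, 150, 400), 1)
    part <- random_part(len, cfg, stream = paste0("rt", i))
    d <- design_part_primers(part, pairs$prefix[i], pairs$suffix[i])
    entry <- make_entry_vector(cfg, d$fusion5, d$fusion3)
    prod <- simulate_level0(part, pairs$prefix[i], pairs$suffix[i],
                            entry, d$forward[1, ], d$reverse[1, ])
    expect_equal(dna_length(prod), 300L + len + 8L)
  }
})
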