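test_that("digestion computes fragments from cut geometry", {
  # linear, no sites: identity fragment with blunt ends
  f <- digest(dna("ACACACACAC"), "BsmBI")
  expect_equal(nrow(f), 1L)
  expect_true(is.na(f$left_end) && is.na(f$right_end))
  expect_equal(f$core, "ACACACACAC")

  # linear, one BsmBI site: hand-checked cut 1 nt downstream, 4-nt overhang
  f <- digest(dna("AAACGTCTCATTTTGGGGG"), "BsmBI")
  expect_equal(nrow(f), 2L)
  expect_equal(f$core[1], "AAACGTCTCA")
  expect_equal(f$right_end[1], "TTTT")
  expect_equal(f$left_end[2], "TTTT")
  expect_equal(f$core[2], "GGGGG")

  # circular entry vector: exactly backbone + dropout
  cfg <- fixture_config(seed = 3)
  f <- digest(make_entry_vector(cfg, "TATG", "ATCC"), "BsmBI")
  expect_equal(nrow(f), 2L)

  # circular molecule with one BsaI site: one linear fragment whose two
  # sticky ends are the same 4-mer (verified by hand on a 40-nt toy)
  toy <- paste0("GGTCTC", "A", "TTAC", strrep("C", 29))
  f <- digest(dna(toy, topology = "circular"), "BsaI")
  expect_equal(nrow(f), 1L)
  expect_equal(f$left_end, "TTAC")
  expect_equal(f$right_end, "TTAC")
  expect_equal(nchar(f$core) + 4L, nchar(toy))
})

test_that("overlapping cut windows are an ambiguous digest", {
  # two opposing BsmBI sites whose 4-nt windows collide head-on
  s <- paste0("CGTCTC", "A", "TG", "T", "GAGACG")
  expect_error(digest(dna(s), "BsmBI"), "[Aa]mbiguous",
               class = "mocloforge_error_assembly")
})

test_that("3'-overhang and multi-enzyme digests are refused", {
  expect_error(digest(dna("AACTGCAGAA"), "PstI"),
               class = "mocloforge_error_validation")
  expect_error(digest(dna("ACGT"), c("BsaI", "BsmBI")),
               class = "mocloforge_error_validation")
})

test_that("digestion conserves bases on random molecules", {
  set.seed(71)
  for (i in 1:60) {
    n_sites <- sample(0:4, 1)
    circ <- i %% 2 == 0
    pieces <- replicate(n_sites + 1, rand_seq(sample(10:60, 1)))
    site <- function() paste0("CGTCTC", "A")  # cuts into what follows
    s <- paste0(paste0(pieces[-(n_sites + 1)], site(), collapse = ""),
                pieces[n_sites + 1])
    mol <- dna(s, topology = if (circ) "circular" else "linear")
    f <- tryCatch(digest(mol, "BsmBI"),
                  mocloforge_error_assembly = function(e) NULL)
    if (is.null(f)) next  # window fell off a linear end or overlapped
    ov <- f$right_end[!is.na(f$right_end)]
    if (!circ) {
      total <- sum(nchar(f$core)) + 4L * length(ov)
    } else {
      total <- sum(nchar(f$core)) + 4L * nrow(f)
    }
    expect_equal(total, nchar(s))
  }
})

test_that("golden gate returns the unique BsmBI-free product", {
  cfg <- fixture_config(seed = 8)
  entry <- make_entry_vector(cfg, "TATG", "ATCC")
  part <- random_part(60, cfg)
  amplicon <- dna(paste0("AACGTCTCA", "TATG", part, "ATCC", "TGAGACGTT"))
  res <- golden_gate(list(amplicon = amplicon, entry = entry), "BsmBI")
  expect_s3_class(res, "assembly_result")
  expect_equal(dna_topology(res$product), "circular")
  expect_equal(dna_length(res$product), 300L + 60L + 8L)
  expect_equal(nrow(scan_sites(res$product, "BsmBI")), 0L)
  # product is inert: redigesting returns it uncut
  f <- digest(res$product, "BsmBI")
  expect_equal(nrow(f), 0L)
  expect_true(isTRUE(attr(f, "uncut")))
})

test_that("constructed ambiguity is reported as such", {
  cfg <- fixture_config(seed = 13)
  entry <- make_entry_vector(cfg, "TATG", "ATCC")
  # two inserts sharing identical end pairs: either can close the circle
  a1 <- dna(paste0("AACGTCTCA", "TATG", random_part(30, cfg, "a1"), "ATCC", "TGAGACGTT"))
  a2 <- dna(paste0("AACGTCTCA", "TATG", random_part(30, cfg, "a2"), "ATCC", "TGAGACGTT"))
  expect_error(golden_gate(list(a1 = a1, a2 = a2, entry = entry), "BsmBI"),
               class = "mocloforge_error_ambiguous_assembly")
})

test_that("a lone vector re-ligates to itself with a diagnostic", {
  cfg <- fixture_config(seed = 14)
  entry <- make_entry_vector(cfg, "TATG", "ATCC")
  res <- golden_gate(list(entry = entry), "BsmBI")
  expect_equal(canonical_circular(res$product), canonical_circular(entry))
  expect_true(any(grepl("re-ligation", res$diagnostics)))
})

test_that("assembly search agrees with exhaustive enumeration on small instances", {
  set.seed(72)
  pool <- c("TTCT", "ATTG", "CCAT", "TGGA", "ATCG", "GTTA")
  for (i in 1:40) {
    k <- sample(2:4, 1)
    ov <- c(sample(pool, k), NA)
    ov[k + 1] <- ov[1]  # close the circle
    mols <- make_gg_instance(k, ov)
    frs <- dplyr::bind_rows(lapply(seq_along(mols), function(j) {
      digest(mols[[j]], "BsmBI", label = names(mols)[j])
    }))
    oracle <- oracle_products(frs[vapply(seq_len(nrow(frs)), function(j) {
      full <- paste0(ifelse(is.na(frs$left_end[j]), "", frs$left_end[j]),
                     frs$core[j],
                     ifelse(is.na(frs$right_end[j]), "", frs$right_end[j]))
      nrow(scan_sites(dna(full), "BsmBI")) == 0
    }, logical(1)), ])
    if (length(oracle) == 1) {
      res <- golden_gate(mols, "BsmBI")
      expect_equal(canonical_circular(res$product), oracle)
    } else if (length(oracle) == 0) {
      expect_error(golden_gate(mols, "BsmBI"),
                   class = "mocloforge_error_no_assembly")
    } else {
      expect_error(golden_gate(mols, "BsmBI"),
                   class = "mocloforge_error_ambiguous_assembly")
    }
  }
})

test_that("canonical circular form is rotation- and strand-invariant", {
  expect_equal(length(unique(vapply(c("ATGC", "TGCA", "GCAT", "CATG"),
                                    canonical_circular, character(1)))), 1L)
  expect_equal(canonical_circular("AAAA"), "AAAA")
  set.seed(73)
  for (i in 1:40) {
    s <- rand_seq(sample(4:60, 1))
    L <- nchar(s)
    r <- sample(L, 1)
    rot <- paste0(substr(s, r + 1, L), substr(s, 1, r))
    expect_equal(canonical_circular(rot), canonical_circular(s))
    expect_equal(canonical_circular(revcomp(s)), canonical_circular(s))
  }
})

test_that("NotI linearisation handles one, several and zero sites", {
  body <- strrep("AT", 40)
  one <- dna(paste0("GCGGCCGC", body), topology = "circular")
  f <- notI_linearize(one)
  expect_equal(nrow(f), 1L)
  expect_equal(nchar(f$core) + 4L, dna_length(one))

  none <- dna(body, topology = "circular")
  expect_error(notI_linearize(none), class = "mocloforge_error_assembly")

  two <- dna(paste0("GCGGCCGC", body, "GCGGCCGC", strrep("CA", 30)),
             topology = "circular")
  expect_warning(f2 <- notI_linearize(two), "2 NotI")
  expect_equal(nrow(f2), 2L)
})

test_that("PCR simulation is exact-match with tails appended", {
  tmpl <- "ATGCCGTAAGCTTACGGATCATGA"
  # primers binding the two ends with empty tails: identity
  amp <- simulate_pcr(tmpl, list(tail = "", binding = substr(tmpl, 1, 10)),
                      list(tail = "", binding = revcomp(substr(tmpl, 15, 24))))
  expect_equal(as.character(amp), tmpl)
  # tails are appended, reverse tail as reverse complement
  amp <- simulate_pcr(tmpl, list(tail = "GG", binding = substr(tmpl, 1, 10)),
                      list(tail = "TT", binding = revcomp(substr(tmpl, 15, 24))))
  expect_equal(as.character(amp), paste0("GG", tmpl, "AA"))
  # absent or ambiguous binding is an error
  expect_error(simulate_pcr(tmpl, list(tail = "", binding = "GGGGGGGG"),
                            list(tail = "", binding = revcomp(substr(tmpl, 15, 24)))),
               class = "mocloforge_error_pcr")
  expect_error(simulate_pcr("ATATATATATATAT",
                            list(tail = "", binding = "ATAT"),
                            list(tail = "", binding = "ATAT")),
               class = "mocloforge_error_pcr")
})
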