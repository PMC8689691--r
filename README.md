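# mocloforge

Design tools for Golden Gate cloning with the yeast MoClo standard,
backed by an in silico assembly simulator that verifies every design it
emits.

MoClo builds plasmids with type-IIS enzymes (BsaI, BsmBI) that cut at a
fixed offset outside their recognition motif, leaving programmable 4-nt
5′ overhangs ("fusion sites"). Because correctly assembled products no
longer contain the enzyme's sites, a one-pot digestion–ligation reaction
converges on a single plasmid — *if* the design is right. `mocloforge`
automates the two designs that are most error-prone by hand:

* **Part domestication** (`design_part_primers()`, `simulate_level0()`)
  — primers that add `flank·CGTCTC·N·fusion-site` tails so a raw
  sequence can be cloned as a typed level-0 part, with a report of
  internal sites that interfere with MoClo (BsaI, BsmBI), BioBrick
  (EcoRI, XbaI, SpeI, PstI), BglBrick (BglII, BamHI, EcoRI, XhoI) or
  integration cassettes (NotI). Candidates are ranked by Wallace melting
  temperature, `Tm = 2(A+T) + 4(G+C)`, of the binding region.
* **Multiplexed gRNA arrays** (`design_grna_array()`, `verify_array()`)
  — one-step cloning of 2–12 gRNA spacers separated by Csy4 sites: each
  intermediate spacer is split between two PCR fragments at a 4-nt
  junction chosen as close to the spacer's centre as possible, subject
  to the sticky-end conflict rule (two overhangs conflict when they
  share ≥ 3 positionally matching nucleotides in forward or
  reverse-complement orientation). The search is greedy with
  backtracking and deterministic.
* **Assembly simulation** (`digest()`, `golden_gate()`,
  `simulate_pcr()`, `notI_linearize()`) — cut-position arithmetic from
  an editable enzyme registry, sticky-end ligation, and one-pot product
  uniqueness checking; the simulator is the oracle that validates both
  designers by reconstructing the assembled plasmid base by base.

Seeded fixture generators (`random_spacers()`, `make_entry_vector()`,
`make_template()`, `random_part()`) provide synthetic vectors and
templates with the correct geometry, so everything is testable without
any external sequence. A thin CLI (`exec/forge`) wraps the same
functions for shell use.

## Worked example

Design a 3-spacer gRNA array against the packaged template fixture and
verify it by simulated Golden Gate assembly:

```r
library(mocloforge)

cfg     <- fixture_config(seed = 42)
tp      <- make_template(cfg)          # scaffold (76 nt) + separator (28 nt)
spacers <- random_spacers(3, cfg)      # three 20-nt spacers

design <- design_grna_array(spacers, "TTCT", "ATTG",
                            tp$binding_fwd, tp$binding_rev)
design
#> <array_design> 3 spacers -> 2 PCR fragments, 1 split(s)
#> junctions: TTCT GGGG ATTG

tidy(design)[, c("name", "fragment", "orientation", "length", "gc", "tm")]
#> # A tibble: 4 × 6
#>   name    fragment orientation length    gc    tm
#>   <chr>      <int> <chr>        <int> <dbl> <dbl>
#> 1 frag1_F        1 forward         51 0.5      54
#> 2 frag1_R        1 reverse         39 0.444    52
#> 3 frag2_F        2 forward         39 0.5      54
#> 4 frag2_R        2 reverse         51 0.444    52
```

Three spacers need two PCR fragments: the middle spacer is split at a
junction (here `GGGG`, its centred 4-nt window) that conflicts neither
with the vector overhangs `TTCT`/`ATTG` nor with its own reverse
complement. The `length`/`gc`/`tm` columns describe each primer
(thermodynamics computed on the binding region). `glance(design)` shows
the split sits exactly at the spacer centre (`max_centre_deviation` 0).

Simulate the PCRs, BsmBI digestion and ligation into a destination
vector, and recover the insert:

```r
dest   <- make_entry_vector(cfg, "TTCT", "ATTG")
insert <- verify_array(design, tp$template, dest)
insert
#> <dna linear, 268 nt> AACTGCTAAGCATAACGTCAAATGCTCAGTCCCTCATCTGGCAGACTCTCGGGCTGG...
```

268 nt = 3 spacers (60) + 2 template copies (2 × 104): the insert is
exactly `spacer1 · scaffold · separator · spacer2 · scaffold · separator
· spacer3`, with zero inserted or deleted bases — `verify_array()`
errors with a positional diff on any mismatch.

Domesticate a 60-nt part as a type-3 coding part and simulate the
level-0 assembly:

```r
part  <- random_part(60, cfg)
pd    <- design_part_primers(part, "3", "3")   # fusion sites TATG / ATCC
entry <- make_entry_vector(cfg, pd$fusion5, pd$fusion3)
level0 <- simulate_level0(part, "3", "3", entry,
                          pd$forward[1, ], pd$reverse[1, ])
level0
#> <dna circular, 368 nt> AAACAGGTACAGCCTGAACAACATATGACACCAATGATACCCGTTATATGGACCCTT...
```

368 nt = 300-nt backbone + 60-nt part + two 4-nt fusion sites; the
product contains no BsmBI site, so it is inert to further digestion.

## Package layout

* `R/` — sequence primitives and enzyme registry, the two designers,
  the assembly simulator, fixtures, FASTA/TSV/JSON IO, tidy/glance/
  autoplot methods.
* `inst/extdata/` — editable enzyme registry and part-type fusion-site
  tables.
* `vignettes/design-and-simulation.Rmd` — the model, its assumptions,
  parameter defaults, and known limitations.
* `exec/forge` — CLI subcommands `scan-sites`, `part-design`,
  `part-simulate`, `grna-array`, `simulate-assembly`, `fixtures`.
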