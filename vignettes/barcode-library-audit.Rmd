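---
title: "Auditing a DNA barcode reference library: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Auditing a DNA barcode reference library}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(barcodeAudit)
```

## The problem

A DNA barcode reference library links voucher specimens, identified to
morpho-species by a taxonomist, to COI-5P sequences (the 658-bp Folmer
amplicon of mitochondrial cytochrome *c* oxidase I). Its value as an
identification reference depends on an audit that no single tool
performs end to end: vetting the sequences themselves, characterising
the divergence structure, delimiting molecular clusters, confronting
them with the morphological hypotheses, and condensing the outcome into
a per-species reliability statement. `barcodeAudit` implements that
audit as composable stages with a one-call orchestrator,
`run_audit()`.

This vignette is the package's own account of the methods: the models
and their assumptions, the tunable parameters with their defaults and
units, the numerical choices, and the places where the design was
genuinely open.

## Sequence vetting

A genuine mitochondrial protein-coding sequence translates without stop
codons. `translate_screen()` uses the invertebrate mitochondrial genetic
code (NCBI translation table 5, taken from `Biostrings`), under which
TAA and TAG are the only stops and AGA/AGG encode serine — using the
standard code here would flag perfectly good barcodes. Codons containing
ambiguity symbols translate to `X` and are never counted as stops. When
no frame is given, the frame with the fewest stops wins, ties going to
the lowest frame number; a pseudogene (NUMT) typically shows stops in
every frame, so the minimum is the conservative choice.

`compliance_check()` mirrors the minimum standards for a full-length
barcode record: ungapped length at least `min_len` (default 500 bp) and
an `N` fraction below `max_ambig_frac` (default 0.01, flag firing at or
above the threshold), plus a clean translation. Both thresholds are
exposed because different campaigns draw these lines differently.

Indels are located in reference ("Folmer") coordinates by global
pairwise alignment to a gap-free anchor (`anchor_align()`; match 1,
mismatch −1, gap open −5, gap extend −2, all configurable; queries under
50% identity to the anchor are rejected as non-homologous). A maximal
gap run of length L in the reference row is an insertion, reported as
occupying positions p+1..p+L after reference position p; a run in the
query row is a deletion covering the reference positions it spans.
Events whose length is a multiple of 3 preserve the reading frame —
in gastropod COI such codon-sized events are real length variants, not
pseudogene signatures — while any other length adds a `frameshift` QC
flag.

**Numerical choice — canonical indel coordinates.** Relative to a
diverged reference, an indel's position is only defined up to
alignment: a global aligner may park a score-equivalent gap anywhere
within a repeat or an ambiguity region, and substitutions near the
event can tie several placements. `detect_indels()` therefore
re-optimises each gap run locally — among all placements of the run in
a ±10 bp window it keeps the one with the most matching flanking sites,
breaking ties leftmost. This subsumes the usual left-normalisation of
rotation-equivalent gaps and makes coordinates reproducible across
aligner quirks. The synthetic generator records its injected events in
the same canonical frame, which is what makes exact-coordinate recovery
a testable contract (the residual failures are genuine ambiguities where
a neighbouring substitution makes a shifted placement strictly better).

## Distances

`k2p()` implements the Kimura 2-parameter distance,
d = −½ ln[(1 − 2P − Q)√(1 − 2Q)], with P and Q the transition and
transversion fractions. Sites where either sequence carries a gap or a
non-ACGT symbol are excluded pair by pair (*pairwise deletion* rather
than complete deletion: a library-wide column mask would discard most of
the data when a few records are short; the setting is a documented
choice, not a claim about any particular desktop program's default).
Distances are proportions internally; all summaries report percent.

Saturated pairs (log argument ≤ 0) and zero-overlap pairs are
**undefined** (`NA`), excluded from summaries with a warning and never
silently zeroed or capped — capping would bias the reported maxima.
`distance_matrix()` computes all pairs via indicator-matrix products
(exactly equivalent to per-pair evaluation, which the tests verify) and
keeps the per-pair usable-site counts.

`summarize_distances()` aggregates unordered pairs at three ranks:
within species, between congeneric species, and between confamilial
genera. The mean is the simple mean over pairs and the SE its standard
error — the convention for the "N comparisons" and SE columns of such
tables is not standardised, so both the total and the usable pair counts
are reported. Subspecies trinomials are treated as the analysis unit:
grouping uses the full name string. `exclusion_filter()` applies the
usual exclusions before summarising: genus-level and uncertain
identifications (qualifier `sp`/`cf`/`aff`), unnamed records, and
names flagged invalid.

## MOTU delimitation

`motu_cluster()` delimits MOTUs as the connected components of the graph
whose edges join pairs at distance ≤ threshold — single-linkage
clustering, under which membership chains transitively. The default
threshold 0.022 is the 2.2% reference ceiling for within-species
divergence in barcode clustering systems. Two documented choices:

* the comparison is **inclusive** (d ≤ t); the operator is rarely
  printed in the literature, and inclusiveness makes the threshold-zero
  behaviour intuitive (only identical-distance-zero records merge);
* the full refined-single-linkage machinery of BIN assignment (initial
  clustering plus Markov refinement) is **not** implemented, because its
  refinement stage is not reproducibly specified; this module is a
  documented approximation and its clusters are MOTU ids, never real
  BIN URIs.

Undefined distances are treated as above threshold, with a warning.
MOTU ids are dense integers numbered by each cluster's first member, so
output is deterministic and order-stable.

## Concordance and review

`classify_motus()` reproduces cluster-report semantics: a MOTU with one
record is a *singleton*; one whose members carry more than one distinct
morpho-species name is *discordant* (at genus rank if the genera differ,
else species rank); the rest are *concordant*. Genus-level specimens
(qualifier `sp`/`cf`/`aff`) stay members but never enter the
distinct-name count — a half-identified specimen is not evidence of
conflict, and such clusters are precisely where barcode-based
identification (`propagate_id()`) can later supply the name, provided
the cluster's other members agree on a single accepted name whose genus
does not contradict the specimen's own.

`review_motus()` formalises expert review: each discordant MOTU is
re-read after resolving names through a synonym table (idempotent
mapping, cycles rejected); if one accepted name remains, the MOTU
becomes `reclassified_concordant` with the triggering synonym recorded,
otherwise `confirmed_discordant`. Review never touches concordant or
singleton MOTUs. In the percentage of concordant MOTUs, singletons
count as concordant by default (`singletons_as_concordant`): a
singleton contradicts nothing, and this is the convention under which
review arithmetic of the form 23 + 8 + 1 = 32 of 35 is self-consistent;
the switch is exposed rather than hidden because the alternative
reading is defensible.

`match_reference()` stands in for an online identification query with a
local computation: percent identity as 100·(1 − p-distance) over the
mutually usable overlapping sites, hits under `min_overlap` (default
400 bp) dropped, ties broken by hit id. No e-values: on a curated
reference alignment, identity over a known overlap is the quantity a
curator actually reads.

## Grading

`grade_table()` assigns each morpho-species with own records one grade:

| grade | meaning | rule |
|---|---|---|
| A | external concordance | own records share one MOTU with same-named external records, and every record of that name is in it |
| B | internal concordance | single MOTU, ≥3 own specimens, no external records of the name |
| C | sub-optimal concordance | ≥3 own specimens split over >1 MOTU |
| D | insufficient data | 1–2 own specimens, no external match |
| E | discordant | own records co-cluster with a different accepted name, or miss the same-named external records entirely |

The decision order is **E > C > A > B > D**. This resolves combinations
the grade definitions alone leave open — a multi-MOTU species that also
matches external records reads as possible genetic structure (C), and
any name conflict dominates everything (E). Two further choices: a
species with only 1–2 specimens that *does* co-cluster with same-named
external records earns A, because insufficient-data status requires
having no matching sequence available; and since the five rules still
are not exhaustive (e.g. two own specimens split over two MOTUs with no
externals), D is the documented fallback, with the rationale string
saying so. The per-species output carries the inputs to the decision
(`n_specimens_own`, `n_motus_occupied`, `has_external_match`) so every
grade is auditable.

Percentages (A+B share, class shares) are carried at full precision;
display rounding is separate, because published roundings of such
shares are not always internally consistent and the package should not
quietly mimic any one of them.

## Trees

`nj_phenogram()` builds the neighbor-joining phenogram from the K2P
matrix (agglomeration by `ape::nj`; undefined pairs are a hard error
listing the offending pairs). Negative NJ branch lengths, a known
artefact of the algorithm on noisy matrices, are clamped to zero with
the deficit moved to the sister edge so tip-to-tip path lengths are
conserved; the policy can be switched off. `bootstrap_support()`
resamples alignment columns with replacement, rebuilds the tree per
replicate, and reports for each original internal bipartition the
percentage of replicates containing it — seeded, so support values are
exactly reproducible. Bayesian inference is out of scope by design; the
NJ phenogram is the in-scope tree.

## The synthetic generator

`simulate_library()` produces libraries with known truth, and its
defaults are the study conditions the rest of the package is exercised
under: 34 species of 2–6 specimens, intraspecific target 0.8%,
congeneric mean target 13.32%, closest species pairs floored at 20% of
that mean, transition/transversion ratio κ = 2, half the records marked
external. The model:

* **Species tree**: pure-birth topology (`ape::rphylo`). Genera and
  families are clades cut from the tree (average-linkage cut at
  ~3 species per genus, ~2 genera per family), so higher-rank summaries
  reflect the tree. Branch lengths are rescaled so the mean
  between-species-within-genus path equals the congeneric target net of
  the intraspecific contribution (a specimen pair adds one intraspecific
  branch on each side), then terminal branches are lengthened until no
  species pair is closer than `min_inter_frac × inter_divergence`.
* **Sequence evolution**: exact K2P transition probabilities per branch
  (matrix-exponential form, not per-site event simulation) — matching
  the estimation model is what makes parameter-recovery tests sharp. A
  coding constraint re-evolves any frame-1 codon that hits TAA/TAG, so
  clean simulated records pass the translation screen by construction.
* **Within species**: star genealogies with terminal branches
  `intra/2 × U(0.5, 1.5)` — enough to control the realized mean (pair
  expectation equals the intraspecific target) without a full
  coalescent, a documented simplification.
* **Error processes**: cryptic splits duplicate a species into two
  lineages ~3× the 2.2% threshold apart; mislabels swap the full
  taxonomy between records of different species; indels insert or
  delete one codon-aligned 3-bp block (motifs TTG/GGG/GGA, the length
  variants reported in patellogastropod COI), recorded in canonical
  coordinates.

**On guarantees versus realism.** The default floor
(`min_inter_frac = 0.2`) emulates a realistic regime in which the
closest species pair sits near the clustering threshold — under it,
occasional lumping is *expected*, as it is in real libraries. Tests of
the invariant "with a barcode gap, MOTUs equal species exactly" instead
set the floor at 0.6–0.75 of an 8% congeneric mean: the premise of that
invariant is a guaranteed gap, and over a 658-site alignment the K2P
estimate of a true 4–5% divergence fluctuates by ±0.8–0.9% (≈√(d/L)),
so the *realized* minimum must clear the 2.2% threshold with that noise
margin, not just the true minimum. Passing those tests therefore shows
the pipeline is exact when a gap exists; it says nothing about taxa
whose divergences straddle the threshold, which is precisely where the
splitter report and grades C/E direct attention on real data.

Problem sizes in the shipped tests (chosen so the whole suite runs in
well under a minute): 4–10 species × 3–4 specimens for most properties,
20 seeds × 8 species for the gap invariant, ~130 injected indels for
coordinate recovery, 34 species × 2–6 specimens in the acceptance
script's end-to-end audit.

What the generator does **not** emulate: codon-position rate
heterogeneity and selection, realistic base composition, coalescent
structure within species, NUMTs, alignment errors from sequencing
chemistry. Passing on synthetic data demonstrates the audit logic and
the estimators, not robustness to those processes.

## Degenerate inputs and determinism

Empty libraries, single-species libraries (nearest neighbour), fewer
than three taxa (NJ), all-identical sequences (one MOTU), zero-overlap
pairs (undefined distance), and specimens absent from assignments all
either work or fail with named errors — the tests enumerate them. Every
stochastic component (simulation, bootstrap) takes an explicit seed and
is bit-reproducible; `run_audit()` reruns identically for identical
inputs, and its provenance block records parameters and versions.

## Known limitations

* Single-linkage at a fixed threshold is a deliberate, documented
  approximation of BIN-style delimitation; ids are not comparable to
  real BIN registries.
* The grading depends on the own/external annotation; libraries without
  provenance cannot earn grade A.
* The amino-acid profile screen is reported as a metric
  (`aa_profile_divergence()`) without a pass/fail threshold — the
  literature offers no operational cutoff, so imposing one would be
  false precision.
* Published-scale distance summaries can only be recomputed when the
  published sequence data are locally available; the package ships the
  machinery and verifies it on constructed and synthetic data.
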