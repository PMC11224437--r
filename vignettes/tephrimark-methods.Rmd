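---
title: "Methods: simulation-driven phylogenomic marker analysis and diagnostic primer screening"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulation-driven phylogenomic marker analysis and diagnostic primer screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tephrimark)
```

# Scope and model

`tephrimark` implements a genome-scale marker workflow of the kind used in
tephritid (true fruit fly) phylogenomics, where conserved single-copy loci
(BUSCO-, UCE- or AHE-style) are harvested from draft assemblies with a probe
set, assembled into taxon-occupancy supermatrices, compared as gene trees
against a species tree, profiled for phylogenetic informativeness, and —
on the applied side — mined for species-specific diagnostic PCR markers for
quarantine identification. Every stage is driven by a synthetic-genome
generator with complete truth tables, so the whole pipeline is testable on a
desk without any downloads.

The package deliberately does **not** re-implement heavy external inference:
maximum-likelihood tree search, coalescent species-tree estimation,
Bayesian divergence dating and MSA software are out of scope. Where a real
study would run an ML program per locus, `tephrimark` substitutes
distance-based neighbor joining with a column bootstrap — a documented
stand-in that exercises the downstream concordance analysis (Robinson-Foulds
distances, tree-space MDS, support summaries) end to end. Externally
estimated Newick gene trees are accepted anywhere internal estimation would
run.

# The synthetic-data generator

`simulate_dataset()` is first-class, tested code, not a fixture. It emulates:

* a known ultrametric species tree over `n_taxa` (Yule by default:
  exponential waiting times, rescaled so the root-to-tip height equals
  `tree_depth` expected substitutions/site);
* `n_loci` conserved loci evolving along that tree under Jukes-Cantor with a
  per-locus Gamma rate multiplier (shape `per_locus_rate_shape`, mean 1) and
  i.i.d. per-site Gamma multipliers (shape `per_site_rate_shape`);
  substitutions only, **no indels**, so the true per-locus alignments are
  column-exact and no MSA step is needed (probe-anchored columnization in
  `anchor_align()` recovers them exactly);
* per-(locus, taxon) dropout with probability `dropout_prob`, creating the
  taxon-occupancy structure that occupancy filtering is designed around;
* i.i.d. uniform background DNA in which retained locus copies are embedded
  at recorded coordinates on a random strand;
* planted species-specific insertions (`n_unique_regions` per taxon,
  `unique_length` bp of i.i.d. DNA), present in exactly one taxon each —
  the ground truth for the diagnostic screen. An optional decoy mode copies
  one taxon's insertion into another taxon at a configurable per-site
  mutation rate, creating the near-miss case a specificity screen must
  reject.

The probe set is the root sequence of each locus (optionally tiled into
UCE-style baits). Because the per-branch transition probability used by the
simulator is the exact Jukes-Cantor transition matrix, the observed
proportion of differing sites between two leaves at total path length $T$
converges to $p = \tfrac{3}{4}(1 - e^{-4T/3})$; the test suite and the
acceptance script verify this at $T = 0.2$ on 12,000 sites.

## Canonical scenarios and their parameters

Two desk-scale scenarios are used throughout the tests, the acceptance
script and `run_demo()`; their sizes were chosen as the smallest
configurations in which every stage's behaviour is statistically visible.

* **Phylogenomic panel** — 8 taxa, 20 loci of mean 800 bp (sd 200, floored
  at 100), `tree_depth = 0.05`, per-locus rate shape 2, per-site rate shape
  0.5, dropout 0.1, 20 kb background. This emulates a family-level panel:
  divergent enough for informative sites and gene-tree variation, shallow
  enough that universal probes capture nearly every locus (the capture
  recovery check demands ≥ 95%).
* **Diagnostic panel** — 8 taxa, `tree_depth = 0.02`, uniform locus rates
  (`per_locus_rate_shape = Inf`), one 1-kb unique region per taxon.
  Diagnostic screening targets closely related quarantine species whose
  orthologous coding sequence sits far inside the 90% identity threshold of
  the cross-genome exclusion step; at family-level depths, fast loci in
  early-diverging lineages can legitimately exceed 10% divergence from all
  panel members and would surface as "specific" — a real property of such
  screens, but not the regime the marker screen is built for. Site-rate
  variation is kept; locus-rate variation is removed because it only
  modulates that depth confound.
* The **site-rate recovery** experiment uses 27 taxa (the size of a
  realistic family panel), one 2,500-bp locus at depth 0.3 with uniform
  locus rate, where Fitch-based rate estimation has enough resolution to be
  meaningfully tested (Spearman ≥ 0.7 against the true rates).

What the generator does *not* emulate: indels and alignment error, GC and
codon structure, paralogy beyond the planted duplicate mode, introgression
and incomplete lineage sorting, sequencing/assembly error. Passing tests
therefore certify the pipeline's logic and numerics, not robustness to
those real-data complications.

# Locus capture

`match_probes()` replaces an external aligner with an exact k-mer
seed-and-extend matcher: seeds of length `k = 15` on both strands nominate
diagonals; each diagonal is scored by full ungapped alignment, and a hit
requires identity ≥ 0.85 over ≥ 80% of the probe. `N` never matches
anything, which is the conservative choice for a pipeline whose endpoint is
a specificity claim. There is no gapped extension: the simulator is
indel-free, and gapped capture is documented as out of scope. On small
genomes the matcher is tested for exact agreement with a brute-force
sliding-window Hamming scan at the same thresholds.

`dedupe_and_extract()` applies the harvesting convention for duplicate
removal per taxon: a locus whose probes hit more than one region of the
genome is dropped for that taxon only (`DUPLICATE_LOCUS`), and a region
claimed by two loci drops both (`SHARED_REGION`). Surviving loci are
extracted with 400 bp flanks on each side, truncated at contig ends and
flagged; minus-strand captures are reverse-complemented so every sequence
reads in probe orientation. Internally all coordinates are 0-based
half-open on the forward strand; 1-based inclusive coordinates appear only
in written partition files and reports.

`anchor_align()` columnizes the captured copies of a locus by probe-match
offset, padding unattained flanks with gaps. Under the indel-free model
this is exact. Because the simulator's flanks are non-homologous background
(unlike real UCE flanks, which carry signal), downstream matrix and tree
stages use `core_only = TRUE`; with real, homologous flanks the full frame
is the right choice.

# Supermatrices and their statistics

Occupancy filtering keeps a locus iff it has at least
$\lceil \tau \cdot n_\text{taxa} \rceil$ non-empty rows — "at least
$\tau$ occupancy" read literally, evaluated at
$\tau \in \{0.5, 0.75, 0.9, 1.0\}$; locus counts are necessarily
non-increasing in $\tau$ and missing data decreases as $\tau$ tightens.
Trimming uses a single gap-fraction rule (default: drop columns with > 50%
gap/missing), a deliberate, reproducible simplification of trimming
software whose exact mode the workflow leaves unstated. A
parsimony-informative site is a column with ≥ 2 residue states each in ≥ 2
rows; gaps, `?` and ambiguity codes are never states. "Missing data"
counts both `-` and `?` cells — whether gap characters count as missing is
genuinely ambiguous in such reports, so the choice is documented here and
applied consistently.

# Gene trees, Robinson-Foulds and MDS

Distances are Jukes-Cantor corrected mismatch fractions over pairwise
complete columns; saturated pairs ($p \ge 3/4$) are clamped to a ceiling of
5 substitutions/site and flagged rather than propagating `NaN`. Neighbor
joining (via `ape::nj`) clamps negative branch lengths to zero with a flag.
Column-bootstrap supports are the percentage of replicates containing each
internal bipartition of the point tree; internal branches of length zero in
a replicate are collapsed first, so alignments with no signal honestly
report support 0 instead of an artifact of deterministic tie-breaking.

Robinson-Foulds distances are unnormalized symmetric-difference counts of
non-trivial bipartitions (the `multiRF` convention; a normalized variant is
available but off by default). Trees with unequal leaf sets are pruned to
the common leaf set, with a log message — the pragmatic convention when
dropout makes gene trees taxon-incomplete. Classical MDS is implemented as
Torgerson double-centering with eigendecomposition; negative eigenvalues
are clamped to zero before scaling, axes are ordered by eigenvalue, and
each axis is sign-fixed so its first nonzero coordinate is positive, which
makes embeddings reproducible across platforms. On distances from planar
configurations the embedding reproduces all pairwise distances to 1e-9.

# Phylogenetic informativeness

Per-site rates are estimated as Fitch parsimony steps on an ultrametric
reference tree divided by total tree length — a deterministic,
dependency-free estimator chosen over ML rate fitting, validated by
simulation recovery, and normalized to dataset mean 1. Missing characters
enter the Fitch sets as "any state" and contribute no steps. The
informativeness profile is the four-state symmetric-model form
$\phi(t;\lambda) = 16\lambda^2 t\, e^{-4\lambda t}$, maximized over $t$ at
$1/(4\lambda)$ and over $\lambda$ at $1/(2t)$. $\phi$ is a per-unit-time
density: rescaling time by $c$ and rates by $1/c$ maps the profile to
$\phi/c$ with its shape (and the location of the optimum, $t^* \mapsto c\,
t^*$) preserved — that rescaling law, not literal invariance of the value,
is the units-consistency property the tests assert. Total PI is the sum
over sites and loci; the "per locus" view reports the mean over loci, with
a per-locus overlay available. The default time grid is 100 points from 0
to 1.5 times the reference root depth.

# The diagnostic screen

The screen follows the four-step recipe of the applied workflow: (1)
fragment each coding sequence of the target taxon into 200-bp windows at a
50-bp step (`floor((L-200)/50)+1` windows); (2) search every window against
all panel genomes with the same seed-and-extend matcher at 90% identity
over 90% coverage — the specificity-defining knob, stated explicitly
because the original pipeline's aligner settings are not; (3) keep windows
with a hit in the target and none elsewhere, merging overlapping survivors
into maximal specific regions; (4) design primer pairs in each region and
verify them by in-silico PCR.

Primer design is exhaustive within a region (regions are at most a few kb):
primers of 18–27 nt, GC 40–60%, Wallace-rule melting temperature
$T_m = 2(A{+}T) + 4(G{+}C)$ in the 53–60 °C annealing window, pair
$\Delta T_m \le 3$ °C, no mononucleotide run over 4, products of 100–200 bp;
pairs are ranked by distance of the pair $T_m$ from 57 °C, then by
product-size centrality. The Wallace rule was chosen because it is exact,
integer-valued and testable; a nearest-neighbor model could sit behind the
same interface.

In-silico PCR accepts a binding site with at most 2 mismatches and an
exactly matching 3-base 3' end, on either strand; amplicons are convergent
forward/reverse site pairs within a 50–2,000 bp size window. The verdict
mirrors gel-band semantics: `UNIQUE` (one target band, none elsewhere),
`SIZE_DISCRIMINABLE` (off-target bands exist but all differ by ≥ 10 bp, so
the marker still identifies the species when band size is read),
`NON_SPECIFIC`, `FAILED`. On the diagnostic-panel scenario the screen
returns at least one `UNIQUE` pair per taxon, and returns nothing when the
planted unique regions are disabled.

# Configuration, reproducibility and numerics

All randomness flows from one integer seed; per-stage seeds are derived
deterministically (`derive_seed()`), so `run_demo()` reruns are
byte-identical. The run configuration is a nested YAML file mirroring every
knob above; unknown keys are rejected and a resolved snapshot is written
next to the outputs. Degenerate inputs are handled explicitly: empty
occupancy ladders, panels of fewer than four shared taxa (the RF/MDS stage
is skipped with a note), saturated distance pairs, all-gap columns,
regions shorter than the minimum product size, and fragments containing
`N` (skipped, logged).

Known limitations: no indel handling anywhere (capture, alignment, PCR
product sizes); the NJ stand-in underestimates what ML would extract from
the same data; Wallace $T_m$ is crude for long or GC-extreme primers;
specificity verdicts are only as good as the panel — a taxon absent from
the panel can always harbor an unseen binding site.

```{r demo, eval = FALSE}
# the full pipeline on the default desk-scale scenario
res <- run_demo(default_run_config(), out_dir = "demo_out")
res$ladder          # occupancy ladder with PIS and missing-data statistics
autoplot(res$mds, highlight = "species_tree")
autoplot(res$pi)
res$screen$primers  # accepted diagnostic primer pairs with verdicts
```
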