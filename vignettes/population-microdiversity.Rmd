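---
title: "Measuring intrapopulation microdiversity, recruitment and recombination from metagenomic reads"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring intrapopulation microdiversity, recruitment and recombination from metagenomic reads}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope and model

`popmicrodiv` quantifies the evolutionary regime of a sequence-discrete
prokaryotic population — a cloud of closely related strains that recruit
metagenomic reads to one reference genome above a sharp identity
threshold — through four families of statistics:

* **codon-level polymorphism**: per-gene nonsynonymous and synonymous
  polymorphism rates `pN` and `pS`, their ratio `pN/pS`, and the percent
  of polymorphic sites (PPS);
* **recruitment**: normalized abundance (RPKG, reads per kilobase of
  genome per gigabase of metagenome) and read-based average nucleotide
  identity (ANIr);
* **recombination**: the relative rate of recombination to mutation
  (gamma/mu) and the recombination coverage `c` (0 = clonal evolution,
  1 = essentially the whole genome has recombined), inferred from
  correlation profiles over synonymous sites;
* **gene-tree congruence**: how many single-copy genes reproduce
  ("rescue") the branches of a concatenated reference phylogeny.

Real populations of this kind are observed through multi-gigabase ocean
metagenomes; those data are far beyond a desk-scale package, so every
estimator here is validated instead by *parameter recovery* on a built-in
simulator whose ground truth (lineages, classified variants,
recombination events) is known exactly.

# The simulator

`generate_genome()` tiles non-overlapping protein-coding genes (uniform
300–900 bp, multiples of 3, ATG start, no in-frame stop, stop codon end,
random strand) with 50–150 bp intergenic spacers at a controlled GC
content. Because the expected footprint is about 700 bp per gene, the
function refuses configurations with more than `length / 700` genes
rather than emitting a pathologically dense genome.

`evolve_population()` derives `n_lineages` haplotypes from the reference:

* each lineage receives `Poisson(t_i * L)` attempted substitutions at
  uniform positions. With `divergence = "fixed"` every branch length
  `t_i` equals `theta`; with `divergence = "exponential"` the `t_i` are
  drawn from an exponential with mean `theta`, emulating the
  branch-length heterogeneity of a coalescent sample. The distinction
  matters only for linkage statistics (below); both keep the expected
  divergence at `theta`.
* selection is an acceptance step at mutation time, not fitness
  dynamics: a nonsynonymous attempt is accepted with probability
  `omega`, otherwise resampled among the synonymous alternatives of that
  site (discarded if none exist). `omega = 1` is neutrality, `omega = 0`
  perfect purifying selection; intermediate values produce the low
  `pN/pS` regimes typical of marine populations directly, without
  population-dynamic machinery.
* homologous recombination draws `Poisson(rho_over_theta * theta * L)`
  events per lineage — the *expected* mutation count, so that receiving
  recombination is independent of a lineage's own divergence; tying it to
  the realized count would systematically overwrite the most divergent
  lineages and deflate mean diversity. Each event covers a geometric
  fragment (mean `fbar`, minimum 100 bp). Two donor models are provided:
  `"population"` copies the current state of a random co-sampled lineage
  (events applied sequentially in random order), while `"pool"` redraws
  the fragment from an external gene pool at the same divergence
  distribution. The pool model is the regime assumed by
  correlation-profile inference; the population model is kept for
  studying within-sample homogenization, but at saturating event rates it
  is drift-dominated (alleles fix or go extinct after many overwrite
  generations), which destroys the linkage signal any profile-based
  estimator relies on.
* alternatively a fixed `phylogeny` (an `ape` tree with branch lengths
  in substitutions/site) can replace the star model; this is what the
  tree-congruence validation uses, since a star phylogeny has no internal
  branches a gene tree could recover.

Classification of every variant is by direct (re-)translation against the
reference codon context; when several substitutions hit one codon the
observed codon is translated as a whole, matching how the read-based
pipeline classifies codon variants. Codons hit more than once in one
lineage get an extra whole-codon check at mutation time: two individually
synonymous changes can combine into a different amino acid (CGA → AGA →
AGC is Arg → Ser), so a chain step that breaks the codon's amino acid is
itself subjected to the `omega` acceptance rule — this is what makes the
purifying endpoint exact (`omega = 0` leaves every codon's protein
sequence untouched, so no nonsynonymous codon variant can ever be
observed). Duplicate attempts at one site
resolve last-wins, so the per-site substitution probability is
`1 - exp(-theta)` rather than `theta`; analyses that need an exact
divergence (e.g. "uniform 5% identity") invert this with
`theta = -log(1 - 0.05)`.

`simulate_reads()` draws single-end reads from lineages proportionally to
their frequencies (default: geometric weights `0.8^i`, emulating the
uneven strain abundances of real samples), uniform starts, optional
uniform per-base error, and flat Phred qualities consistent with the
error rate. What the simulator does *not* emulate — indels, paired ends,
GC-coverage bias, chimeras, conserved-gene recruitment from unrelated
taxa — bounds what passing tests can show about real data: the pipeline's
*statistics* are validated, not the robustness of short-read alignment to
every real-world artifact.

# Recruitment and microdiversity

Reads pass the standard quality gate (mean Phred >= 30, length >= 50 bp,
no Ns; thresholds inclusive, mean rather than sliding-window quality —
one interpretable scalar) and are placed by an internal ungapped
seed-and-extend aligner (exact 13-mer seeds vote for a diagonal; best
full-length Hamming placement wins; ties to the leftmost position). One
best placement per read avoids double-counting in abundance estimates.
Gapped alignments from external mappers can be imported through a minimal
SAM reader instead; deletion columns score as mismatches. Masked
reference regions — typically the ribosomal operon, which would otherwise
recruit reads from the whole community — are excluded from alignment
scoring and from every length denominator, and reads more than half
inside a mask are dropped.

Recruitment metrics follow their definitions: RPKG divides recruited
reads (98% identity / 50 bp cutoffs) by genome kilobases and metagenome
gigabases, where the metagenome size is always the *source* read set,
never the recruited or subsampled one; a `read_adjusted` mode divides the
metagenome size by its mean read length first, covering the alternative
reading of read-length normalization between sequencing platforms. ANIr
is the median (and mean) per-read identity after an 80%/50 bp cutoff.

Microdiversity statistics are computed per codon from reads spanning all
three codon positions, after subsampling alignments to a fixed depth
(1e6 by default) so that coverage differences between samples cannot
leak into the statistics. A codon variant is valid when observed at
least 4 times, at frequency at least 0.1% of its codon-spanning reads,
at coverage at least 5x (all inclusive; the frequency denominator is
per-codon, the natural reading for per-position variant semantics).
Expected synonymous/nonsynonymous site counts per codon use fractional
site counting over the 9 single-base neighbors (stop-creating changes
count as nonsynonymous; stop reference codons, i.e. terminal stops, are
excluded); `pN = 100 * (codons with a nonsynonymous variant) / N_exp`
and `pS = 100 * (codons with a synonymous variant) / S_exp` over covered
codons. This normalization is what makes the neutral limit come out
right: under `omega = 1` the simulator's uniform-alternative mutation
process matches the equal-rate assumption of fractional site counting,
and genome-median `pN/pS` is ~1 by construction — the module's central
correctness property, verified by the acceptance suite together with the
purifying endpoint (`omega = 0` gives `pN` identically 0) and
coverage-invariance (median `pN/pS` moves by <10% between 1e5 and 1e6
subsampled alignments while mean PPS grows, because deeper sampling
passes rarer variants through the count filter). `pN` and `pS` are
reported per 100 expected sites, which reproduces the magnitude regime
of published per-gene tables (pS up to ~15–20, pN below ~2).

# Recombination from correlation profiles

Over the strictly synonymous sites (third positions of fourfold-
degenerate codons — the cleanest class, as selection cannot shape it),
`correlation_profile()` accumulates, for every pair of masked sites at
distance `l` covered by one read, the product of mismatch indicators
against the reference; `d_sample` is the single-site mismatch rate.
Within-read pairs only: the samples are short single-end reads, so
`max_l` defaults to read length − 1. Reference-based indicators are an
approximation to the read-vs-read formulation; they are what an
alignment set makes computable.

If all lineages had the same divergence, the two-site product would
factorize (`d(l) = d_sample^2` everywhere) and carry no information;
linkage signal exists because lineage divergences vary. With
heterogeneous branch lengths (variance `V`), two sites that share their
ancestral origin contribute `d_sample^2 + V`; sites with different
origins contribute `d_sample^2`. Writing `S(l)` for the probability that
a pair at distance `l` shares its origin under gene-pool recombination
covering each site at rate `R` with geometric fragments (mean `fbar`,
latest event wins), a competing-risks argument gives, with
`u = exp(-l / fbar)`:

    S(l) = exp(-R (2 - u))  +  u / (2 - u) * (1 - exp(-R (2 - u)))

(the first term: neither site ever recombined; the second: both sites
acquired by one and the same event — the ratio `u / (2 - u)` is the
probability that the latest event touching either site covers both, and
is independent of `R`, which is why saturated regimes are distinguished
by `R` only through the vanishing clonal term). `fit_recombination()`
fits `d(l) = d_sample^2 + V * S(l)` by weighted least squares on a
deterministic `(R, fbar)` grid with `V` solved in closed form, and keeps
a nonzero `R` only if it beats the flat clonal model by an F ratio of 8
(about the 0.1% point of the null F distribution) — without this gate,
sparse-pair noise on a genuinely clonal profile is absorbed into a
spurious short-range decay. Derived quantities: recombination coverage
`c = 1 - exp(-R)` and `gamma/mu = R / (d_sample * fbar_hat)`, the event
rate per unit of mutational diversity per correlation block. These are
*relative* rate estimates: the validation grid checks the clonal
endpoint (`c < 0.1`, `gamma/mu ~ 0`), the saturated endpoint
(`c > 0.85`) and strict rank recovery of `gamma/mu` across
`rho_over_theta` in {0, 5, 20}, not absolute equality with the
generator's parameters.

The validation conditions were chosen once, from the estimator's
operating requirements, and are deliberately specific: exponential
branch-length heterogeneity (fixed divergence has zero linkage signal);
the pool donor model (the model the estimator assumes; within-population
donation at saturating rates is drift-dominated and carries no stable
signal); `theta = 0.0017` with `fbar = 100` so that the intermediate
level `rho_over_theta = 5` stays clearly below coverage saturation
(`R ~ 0.85`) while level 20 saturates (`R ~ 3.4`); a 300 kb gene-dense
genome at GC 0.60 (fourfold-degenerate sites are GC-rich codon families,
so this roughly doubles the mask density), 400 lineages and 7e5 reads of
400 bp so that the number of distinct (site-pair, lineage) co-occurrence
events — the real unit of information, which no amount of extra read
depth can multiply — supports the fit. These sizes keep one grid of
3 levels x 5 seeds within a few minutes of compute.

# Gene-tree congruence

`select_single_copy()` clusters genes greedily by anchored ungapped
identity (70% identity over 80% of the shorter length, seeds = longest
sequences — the cd-hit recipe at desk scale) and keeps clusters with
exactly one member per genome. Gene trees and the concatenated reference
tree are neighbor-joining on raw p-distances, with alignment columns
under 80% site coverage removed and negative branch lengths clamped to
zero; distance/NJ topologies replace maximum-likelihood inference
because the congruence statistic consumes topologies, not support
values. A gene "rescues" a focal reference bipartition iff that
bipartition occurs in its own bipartition set; Robinson–Foulds distances
are computed from the same bipartition sets (and cross-checked against
an independent implementation in the tests). Focal branches are
user-specified (the deepest splits, in published practice); by default
all non-trivial reference bipartitions are scored. Validation evolves
six taxa down a known balanced tree (internal branches 0.03
substitutions/site, so each ~500 bp gene carries ~15 informative
substitutions per branch): without recombination at least 95% of 50 gene
trees must rescue every branch, and transferring 20 genes between clades
with `transfer_genes()` must create conflicts at the affected branches.

# Numerical and design choices

* Coordinates are 0-based half-open internally; BED is native, GFF3 and
  SAM convert at the file boundary. Masking is carried as an interval
  set; the sequence is never rewritten, so coordinates stay stable.
* All randomness is drawn from R's RNG under caller-supplied seeds;
  compiled code only applies pre-drawn events. Identical seeds give
  byte-identical outputs end to end (`run_pipeline()` is covered by a
  byte-determinism test).
* The aligner requires one exact 13-mer seed; at 8% divergence a 100 bp
  read still seeds with probability ~1 - (1 - 0.92^13)^8 > 0.97, and the
  populations of interest sit well above 90% identity.
* Ambiguity decisions: mean-Phred QC (per-base vs mean is unstated in
  common protocols; the flag `min_phred` documents the choice); per-codon
  frequency denominator for the 0.1% filter; both RPKG normalization
  readings behind `norm_mode`; best-hit-only ANIr.
* `pN/pS` is undefined (NA) for genes with `pS = 0`; genome summaries
  use the median over defined genes plus the fraction of genes above 1,
  and per-gene tables are always emitted so any other aggregation can be
  recomputed.
* Known limitations: no indels or paired ends; ungapped internal
  alignment (imported SAM covers gapped data); reference-based mismatch
  indicators in the correlation profile; star or fixed-tree lineage
  structure rather than a coalescent; `c` and `gamma/mu` are
  model-derived relative quantities, not absolute rates.

# Problem sizes used in the validation suite

Simulations in the tests and the acceptance script use genomes of
20–300 kb, 10–400 lineages and 2e4–1.6e6 reads; these sizes were chosen
as the smallest at which each property's signal clearly exceeds its
sampling noise (pair sparsity for the correlation profile, count filters
for the depth-invariance check), and they complete in minutes on a
single core.
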