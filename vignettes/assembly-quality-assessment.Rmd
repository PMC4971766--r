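---
title: "Reference-free quality assessment of de novo transcriptome assemblies"
author: "transqc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reference-free quality assessment of de novo transcriptome assemblies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(transqc)
```

## The problem

A de novo transcriptome assembly is built from nothing but the reads, so its
quality cannot be judged against a reference that, by assumption, does not
exist. `transqc` evaluates an assembly using only those same reads: the read
pairs are placed on the contigs, multi-mapping pairs are resolved
probabilistically, and the placements are interrogated for the signatures of
the common assembly artifacts — base-level errors and hybrid gene-family
contigs (disagreement between reads and contig sequence), incompleteness
(uncovered bases, pairs with one mate falling off an end), structural errors
(pairs in impossible orientations or at impossible distances, pairs bridging
two contigs), and chimeras (an abrupt change of coverage level along the
contig).

## The scores

Each contig $C$ with assigned read set $R$ receives four components, each in
$[0, 1]$:

* $s(C_\mathrm{nuc})$ — per-base agreement between reads and contig. Every
  read $r$ carries an alignment edit distance $e_r$ (the SAM `NM` tag, or the
  simulator's injected-substitution count), capped by the reporting limit
  $\hat e$ (default 30). Each read supports each nucleotide it covers with
  weight $1 - e_r/\hat e$, and $s(C_\mathrm{nuc})$ is the mean of all these
  per-read-per-nucleotide support values — that is, coverage-weighted, so a
  disagreement under deep coverage counts once per offending read, not once
  per base.
* $s(C_\mathrm{cov})$ — the fraction of the contig's nucleotides covered by
  at least one aligned mate, regardless of agreement.
* $s(C_\mathrm{ord})$ — the fraction of pairs touching the contig that are
  *proper*: both mates on this contig, relative orientation matching the
  library model, and implied fragment size inside the inferred window. Pairs
  bridging two contigs count against both (they are the fragmentation
  signal); pairs with one unaligned mate count against the contig holding
  the aligned mate.
* $s(C_\mathrm{seg})$ — the posterior probability that the coverage profile
  is one segment rather than several (the chimera test; below).

The contig score is their product,
$s(C) = s(C_\mathrm{nuc})\,s(C_\mathrm{cov})\,s(C_\mathrm{ord})\,s(C_\mathrm{seg})$,
with each factor floored at 0.01 so a single failed component saturates at a
minimum value rather than annihilating assembly-level statistics; the
assembly score is

$$T = \Big(\prod_{c=1}^{n} s(C_c)\Big)^{1/n} \; R_\mathrm{valid},$$

the geometric mean of the contig scores times the fraction of input read
pairs with both mates aligned. The geometric mean makes every contig, not
every read, count equally. The abundance-weighted variants raise each contig
score to $1 + \log_n(\mathrm{TPM}+1)$ (base $n$ = number of contigs), so
abundant contigs are penalized more for the same defects; weighted scores
are not comparable between contigs and are reported separately.

## Read-pair processing

**Placement collection.** Alignments are accepted from BAM/SAM (`NM` tags
required) or from a TSV interchange format the bundled simulator writes, so
the full pipeline runs with no external aligner. Per pair, up to 10 candidate
placements are kept, all within a summed-mate edit distance of 5 of the best
placement — the reporting contract of a typical multi-mapping short-read
aligner. Coordinates are 0-based half-open internally; SAM input is converted
on read.

**Library model.** From a seeded uniform subsample of pairs whose mates land
on one contig (1% of mapped pairs, floored at 1000), the modal relative
orientation and the mean and standard deviation of the implied fragment size
are estimated. The proper-pair window is `fragment_mean ± k_sd · fragment_sd`
with `k_sd = 3.5`. The window is deliberately wider than the ±3 sd band a
size-selected library occupies: the sd is itself estimated from a subsample,
and a 3.0 sd window would misclassify correctly sequenced pairs near the band
edge purely through estimation noise.

**Abundance EM and assignment.** Multi-mapping pairs are resolved in two
stages. First, abundances: the responsibility of contig $c$ for a pair is
proportional to $\theta_c/\tilde\ell_c$ summed over its candidate placements
on $c$, where $\tilde\ell_c = \max(\ell_c - \bar f + 1, 1)$ is the effective
number of fragment start positions; the M-step sets $\theta \propto$ summed
responsibilities; iteration starts from uniform $\theta$ and stops when
$\max|\Delta\theta| < 10^{-6}$ (cap 1000 iterations). The responsibility
model uses abundance and effective length only — no alignment-error term —
because evaluation-time assignment is defined as sampling from relative
abundances. Second, assignment: each mapped pair is assigned entirely to one
contig, drawn once from its final responsibilities with a seeded generator
(uniquely mapping pairs deterministically; a uniform draw if every
candidate's abundance collapsed to zero). Contig evaluation then uses these
all-or-nothing assignments, so a redundant contig whose reads are captured
by a better copy genuinely loses them.

## The chimera test

A contig concatenating two transcripts expressed at different levels shows a
change-point in coverage depth. Depth is encoded as symbols
$\mathrm{round}(\log_2(\bar d + 1))$ (the $+1$ makes zero depth a valid
symbol), the alphabet being shared across the whole assembly so scores are
comparable. For $k = 1, \dots, k_\mathrm{max}$ (default 2) the marginal
likelihood of the symbol sequence under $k$ contiguous segments — each an
independent Dirichlet-multinomial with symmetric concentration $\alpha = 1$,
averaged over the $\binom{L-1}{k-1}$ change-point placements — is computed
exactly by dynamic programming in log space, and
$s(C_\mathrm{seg}) = P(k = 1 \mid x)$ under a uniform prior over $k$. The DP
is validated against exhaustive enumeration over all segmentations for short
sequences.

Two pre-processing choices matter and were set by calibration on simulated
data before the validation experiments were frozen:

* **Edge trimming.** Paired-end coverage is deterministically non-stationary
  within about one fragment length of each contig end (mate spans pile up in
  fragment-geometry patterns there). One inferred fragment length is trimmed
  from each end before encoding, capped at a quarter of the contig.
* **Binning.** Depth is averaged in windows so that a contig yields about 20
  symbols. Coverage is autocorrelated on the scale of a read, so
  per-nucleotide symbols are not independent draws: runs created by rounding
  noise at symbol-band edges are then always better fit by two segments, and
  the posterior collapses to ~0 for perfectly correct contigs. Wide bins
  restore approximate independence while leaving a fusion junction visible
  as a block of differing symbols.

With these defaults, correct contigs score $s(C_\mathrm{seg}) \approx 0.9$,
and in the bundled fusion experiment the smallest abundance-ratio bin whose
fusions drop below the 10th percentile of non-fused contigs is the twofold
bin; equal-abundance fusions are indistinguishable, since without an
abundance difference there is no coverage step to find. Note the ceiling:
$P(k=1\mid x)$ is a posterior over $\{1,\dots,k_\mathrm{max}\}$ and is
strictly below 1 for any finite profile (about 0.975 for a perfectly
homogeneous 20-symbol profile). Consequently a perfect assembly scores
slightly below the ideal $T = 1$; the bundled ideal-data experiment yields
$T \approx 0.89$, with the support, order and mapping-rate factors exactly 1
and the shortfall coming from the segmentation posterior and the handful of
uncovered bases that finite sampling of exponentially distributed abundances
always leaves on the lowest-abundance transcripts.

## Cutoff learning and filtering

The assembly score as a function of a retention cutoff on contig score is
piecewise-constant, so the learned cutoff is found by an exact sweep over the
distinct contig scores (plus 0): retain $\{s \ge t\}$, recompute the mapping
rate as the fraction of all input pairs that are both-mates-mapped *and*
assigned to a retained contig, and keep the $t$ maximizing the filtered
score, ties resolved toward retaining more contigs. Pairs are not re-assigned
after filtering — re-running the EM inside the optimizer would change the
objective mid-search; this is a deliberate approximation, and the optimized
score is never below the raw score because $t = 0$ is always a candidate.

## Reference-based validation

When the true transcripts are known (here: because reads are simulated),
contig accuracy is measured as the F-score of reciprocal best hits:
Smith–Waterman local alignment (match +1, mismatch −2, gap open 5, gap
extend 2), mutual best hits kept, with a minimum alignment score of 50
standing in for a database-size-dependent e-value threshold at this scale;
precision = identical aligned bases over contig length, recall = the same
over reference length. Only pairs sharing at least one 15-mer are aligned
(a seed-and-extend-style prefilter, tested against the exhaustive mode);
identity counts come from the single best local alignment, not summed over
multiple local hits. On a mixed-corruption simulated assembly the Spearman
correlation between contig score and F-score exceeds 0.5 (the bundled
experiment gives ≈0.7), with the residual scatter dominated by accurately
assembled low-abundance contigs: their F-score is high but their
reference-free evidence is thin — the same confound the score is designed to
expose in real data.

## The simulator

The generator exists so that every stage is testable end-to-end with no
downloads and no aligner. It emulates: a transcript set with log-normal
lengths (default meanlog `log(1600)`, sdlog 0.35, floored at 250 nt —
preserving the roughly 4:1 transcript-to-insert length ratio of real
transcriptomes; shrinking transcripts toward the insert length makes
paired-end coverage deterministically bimodal and is not representative),
exponentially distributed abundances normalized to 1, and paired 100 nt
reads from fragments of Normal(400, 50) size truncated to the selection band
`[max(2·read_length, mean − 3sd), min(mean + 3sd, transcript length)]` — a
gel size-selection model; fragment starts are uniform; source transcripts
are drawn proportional to abundance × length (fragment mass); substitution
errors are i.i.d. per base (default 1%) and counted exactly into the truth
`NM`. The truth table doubles as the alignment input, which reproduces what
an exact mapper would report.

What it does **not** emulate: positional or GC bias, indels, quality-score
structure, intron contamination, or an actual de Bruijn assembler. Passing
tests therefore demonstrate the correctness and discriminative behavior of
the scoring machinery on data satisfying the library model's assumptions,
not robustness to every artifact of real libraries.

Fusions (`make_chimeras`) concatenate transcript pairs head-to-tail and
replace their constituents, pairing either uniformly at random (the
validation-faithful default) or greedily to hit target abundance ratios.
Corruptions (`corrupt_assembly`) apply unsupported insertions, 3'
truncations, fusions and substring duplications, and `lift_alignments`
re-addresses the ground-truth placements the way a mapper would report them:
reads spanning an insertion are charged one edit per base extending into the
insert (dropped past the reporting cap), mates extending past a truncation
become unaligned, duplicated windows add a second candidate placement.

Two measured caveats are worth recording. Truncating a contig usually lowers
its order score (pairs spanning the cut lose a mate) but can slightly
*raise* the covered fraction, because the handful of hard-to-cover terminal
bases leaves with the tail; the sign-definite way to degrade
$s(C_\mathrm{cov})$ is read downsampling, which the tests use. Similarly, an
insertion can evict error-bearing reads and thereby nudge the support score
up when reads carry sequencing errors; the monotonicity tests use error-free
reads so that they measure the corruption, not the noise.

## Parameters at a glance

| parameter | default | meaning |
|---|---|---|
| `max_edit_distance` | 30 | reporting cap $\hat e$, support normalizer |
| `max_placements`, `placement_edit_window` | 10, 5 | multi-mapper reporting contract |
| `subsample_fraction` | 0.01 (floor 1000 pairs) | library-model subsample |
| `k_sd` | 3.5 | proper-pair fragment window, in sd units |
| `k_max`, `alpha` | 2, 1 | segment count ceiling, Dirichlet concentration |
| `segment_bins`, `edge_trim` | 20, one fragment length | coverage encoding |
| `floor` | 0.01 | component floor before the product |
| `tol`, `max_iter` | 1e-6, 1000 | EM stopping rule |

Degenerate inputs are handled explicitly: contigs that acquire no evidence
score 0 on every component (then floored), an empty candidate set leaves a
pair unassigned, orientation ties resolve to the lexicographically first
label with a warning, zero-responsibility draws fall back to uniform, and a
single-symbol alphabet has marginal likelihood 1.

## Reproducing the bundled experiments

The testthat suite regenerates every dataset it uses. The ideal-data
assembly score is recomputed from scratch by `scripts/acceptance.R`
(`Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json`),
which simulates the 50-transcript, 20,000-pair error-free experiment and
runs the full pipeline on the true transcriptome. Problem sizes throughout
(50–200 transcripts, 20,000–100,000 pairs, 20 monotonicity replicates) are
the package's chosen desk scale: large enough for the distributional
statements above, small enough to rerun while iterating.
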