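---
title: "Detecting cis-regulatory modules from motif density: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting cis-regulatory modules from motif density}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem and the model

Cis-regulatory modules (CRMs) — enhancers, silencers, locus control regions,
promoter-proximal elements — are genomic segments in which transcription
factor binding sites (TFBSs) cluster to control gene expression. Empirical
assays (ATAC-seq, ChIP-seq, reporter assays) sample only the cell types and
conditions that were actually assayed. `crmdetect` implements the
complementary, training-data-free route: if a position weight matrix (PWM)
library summarises the binding preferences of the transcription factor
repertoire, then regions of a genome where predicted binding sites pile up
significantly above the chromosomal average are candidate CRMs, regardless
of when or where they are active.

The procedure has four stages.

**1. Site calling.** Every window of every sequence is scored on both
strands with each PWM as a log-likelihood ratio in nats,
$S(w) = \sum_i \ln \frac{f_i(w_i)}{q(w_i)}$, with smoothed frequencies
$f_i(b) = (n_i(b) + p\,q_b)/(N_i + p)$. Windows containing ambiguous bases
(N) are unscorable. The per-motif cutoff is the classic automatic rule tied
to information content: the smallest lattice score $s$ with
$\ln P(S \ge s) \le -IC$ (IC in nats), where $P$ is the exact
score distribution of a background window, obtained by discretising each
column's four scores onto a lattice of width `bin_width` and convolving
columns. Sharper motifs therefore demand rarer scores. The discretisation
error is at most `bin_width/2` per column; the default `bin_width = 0.01`
nats keeps the relative threshold error well under 1% for typical motifs.

**2. Density Z-scores.** For each sequence record the per-position count of
covering sites $c(i)$ is standardised, $Z(i) = (c(i)-\mu)/\sigma$, with
$\mu, \sigma$ the mean and *population* standard deviation over non-N
positions. The census interpretation (divide-by-$n$) is deliberate: a
chromosome is the entire population of positions, not a sample, and the
choice must be fixed for tests even though the difference vanishes at
genome scale. A constant track (e.g. a record with no sites) has no
Z-scores; the caller emits zero CRMs for it with a warning.

**3. Seeded, gap-limited extension.** Positions with $Z > 2.33$ — the
one-tailed standard-normal 0.01 quantile, the method's single tunable
parameter — are seeds. A seed extends in both directions along "stepping
stone" positions with $Z > 0$, hopping to the next one whenever it lies
fewer than `max_gap = 30` bases away (the longest motif length in the
intended library) and no N lies between. Boundaries are the outermost
$Z > 0$ positions reached, so flanking positions have $Z \le 0$: the
zero-crossing boundary rule. Seeds absorbed by an earlier extension do not
re-seed. Operationally this is a partition of $Z>0$ positions into chains
under the (`< max_gap`, no-N) adjacency; each chain containing a seed is
one CRM. "Fewer than 30 away" is read strictly (`diff < max_gap`), and a
CRM never spans an N run (it splits there) because masked positions are
excluded from $\mu/\sigma$ and cannot be stepping stones.

**4. Matched controls and evaluation.** Claims of enrichment need a
baseline with identical length structure. The control scheme: complement
the full CRM set per sequence; drop complement regions that are more than
50% N; drop regions shorter than 400 bp lying *between* two CRMs (they may
be mis-bounded CRM margins — terminal regions are exempt, since the rule
names regions between two predictions); take the CRM subset shorter than
250 bp (strict), lowering the cap in 10 bp steps if the space cannot host
the multiset; trim each candidate by 40 bp per end; and carve fragments
with exactly the CRMsub length multiset, 5 bp apart. Carving is
longest-first into the candidate with the largest remaining capacity;
within a candidate, fragments are left-packed after one uniform random
start jitter. The multiset equality, zero overlap with all CRMs, and
determinism under one seed are hard invariants tested on every fixture.

Detection is then a 2x2 table over a reference region set (each reference
hit/missed by predictions and, independently, by controls) at either of two
overlap cutoffs: at least 1 bp, or at least 50% of the shorter fragment.
The table yields sensitivities, an odds ratio $ad/bc$ (Haldane–Anscombe
+0.5 on all cells only when a cell is zero), a 95% Woolf log-normal CI, and
a Pearson chi-square p-value *without* continuity correction — the
uncorrected test is what reproduces the published bounds on the published
tables. Because a full prediction set can out-cover any control set, the
package also provides a positional-shuffle null: every prediction is
repositioned uniformly at random within its own sequence (lengths kept,
overlaps among shuffled intervals allowed — independence keeps the null
exchangeable and cheap), and the add-one empirical p-value
$(1 + \#\{\text{null} \ge \text{obs}\})/(R+1)$ never returns zero at
finite replicates.

## Motif-library consolidation

De novo motif discovery returns heavily redundant PWM sets. Redundancy is
resolved with the average log-likelihood ratio statistic between aligned
columns,

$$\mathrm{ALLR} = \frac{\sum_b n_b^{(2)} \ln(p_b^{(1)}/q_b) +
\sum_b n_b^{(1)} \ln(p_b^{(2)}/q_b)}{n^{(1)} + n^{(2)}},$$

summed over the best ungapped alignment across all offsets and both
orientations. Two motifs are redundant when the best alignment has summed
ALLR > 6.57 *and* OLAP > 68.1% — OLAP being aligned columns as a
percentage of the shorter motif (the shorter-matrix denominator lets a
sub-motif be absorbed by its parent, which is the point of consolidation).
Consolidation is greedy: rank by `total_score` (information content times
length when no discovery score is available; ties broken by id), keep the
top, delete everything redundant to it, recurse. The procedure is
idempotent, and a minimum overlap of 5 columns — the shortest library
motif — keeps ALLR estimates stable.

## What the synthetic generator emulates — and what it does not

`simulate_genome()` produces the stated world the tests run in: i.i.d.
background sequence (uniform by default; an order-1 Markov texture is *not*
default because the scanner's background model is i.i.d.), into which
clusters of motif-sampled sites are implanted. Defaults mirror the
validation scale used throughout: a 100 kb record, 20 clusters of
150–250 bp separated by at least 200 bp, 6–12 non-overlapping sites per
cluster drawn from the motif's smoothed frequency model (not its consensus,
so site scores vary realistically and a realistic fraction falls below the
automatic cutoff), random strands, optional N runs, all deterministic under
one seed. `dinuc_shuffle()` provides the matched negative: an
Altschul–Erickson Eulerian-walk shuffle preserving exact mono- and
dinucleotide counts while destroying clustering.

A green end-to-end test therefore establishes that the pipeline recovers
planted density signal against an i.i.d. background at desk scale. It does
not establish performance on real chromatin: repeats, isochore composition
drift, soft-masked regions and the 5,000-motif scale of a real library are
all outside the generator's world, and genome-scale coverage figures
cannot be reproduced here.

## Numerical choices and degenerate inputs

* Score lattice `bin_width = 0.01` nats; impossible outcomes under a
  pseudocount-free motif (zero smoothed frequency) are carried as a
  sentinel mass below every attainable finite score so survival queries
  stay exact at finite thresholds.
* Pseudocount `p = 0.375`, background-proportional, the long-standing
  Patser convention; background defaults to uniform.
* A zero-information motif passes every window: threshold = minimum score,
  with a warning.
* Palindromic double-hits count twice (strands are scanned independently);
  per-position counts are *coverage* (a site adds 1 to every position it
  spans) rather than site starts — occupancy reads most naturally as
  "sites per position" and makes the zero-crossing boundary well defined at
  site edges; `count_mode = "starts"` is available for sensitivity
  analysis.
* All coordinates are 0-based half-open (BED) end to end; interval algebra
  is delegated to IRanges behind that convention.
* Every stochastic stage (carving jitter, shuffle null, generator) draws
  from a sub-seed derived from the single user seed by a stable string
  hash, under a saved-and-restored RNG state.

## Known limitations

* Per-sequence statistics make short records noisy; records with fewer
  than two unmasked positions or constant coverage yield no calls.
* The shuffle null treats predictions as independent; a non-overlap
  constraint would slightly thin the null's upper tail.
* Control carving matches lengths globally with capacity-based candidate
  choice; it does not match GC or repeat content, and per-chromosome
  matching is attempted only implicitly through capacity.
* Feature annotation is a fixed precedence ladder (Promoter within 3 kb of
  a TSS, then UTRs, exon, intron, 3 kb downstream, distal intergenic) over
  transcript-level inputs; it is intentionally simpler than a full
  annotation engine.

## A worked miniature

```{r, eval = FALSE}
library(crmdetect)
motif <- demo_cluster_motif()
cfg <- sim_config(seq_length = 100000, n_clusters = 20,
                  motif_ids = motif$id, seed = 1)
sim <- simulate_genome(cfg, list(motif))
res <- run_crm_caller(sim$sequence, list(motif))
plan <- build_control_plan(res$crms, c(sim1 = 100000L), seed = 1)
evaluate_overlap(prepare_reference(sim$truth), plan$crmsub,
                 plan$controls, "one_bp")
```

The same computation runs, with logging, via
`Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json`.
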