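---
title: "Methods: DSB cluster calling, R-loop kinetics, and overlap enrichment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: DSB cluster calling, R-loop kinetics, and overlap enrichment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dsbrloop)
```

# Scope and model

`dsbrloop` analyses two sequencing readouts of topoisomerase-I-poison
treatment. END-seq captures blunted DNA ends, so a double-strand break
appears as a reverse-strand (minus) peak on its left and a forward-strand
(plus) peak on its right; DRIP-seq captures DNA-RNA hybrids as peaks whose
abundance changes over treatment time. Everything downstream of aligned,
peak-called data is in scope: pairing strand peaks into break clusters,
replicate consensus, spike-in normalization, differential enrichment,
kinetic classification, single-ended break detection, and
randomization-based overlap statistics. Peak calling itself is assumed
done upstream (a deliberately simple threshold caller,
`call_strand_peaks()`, exists for coverage tracks, but it is not a
model-based caller and external peaks are first-class input).

All intervals live in `GRanges` with a `Seqinfo` genome dictionary;
files use the BED convention (0-based, half-open). Internally GRanges
coordinates are 1-based closed; conversion happens only at I/O
boundaries.

# Pairing strand peaks into DSB clusters

For each reverse peak $r$ the closest forward peak $f$ is found under the
signed distance

$$d(r, f) = \begin{cases}
 f_\text{start} - r_\text{end} & f \text{ starts at or beyond } r_\text{end} \\
 0 & f \text{ and } r \text{ overlap} \\
 -(r_\text{start} - f_\text{end}) & f \text{ entirely left of } r
\end{cases}$$

and the pair is kept iff $0 \le d < 150$ bp (the gate is exclusive: a
150-bp gap is discarded). The cluster spans $[r_\text{start},
f_\text{end})$. The biology behind the overlap-at-zero convention: END-seq
end-blunting makes abutting or slightly overlapping flank peaks the
expected geometry right at a break, so only genuinely wrong-sided forward
peaks ("negative distance") are rejected.

Decisions where the procedure was underdetermined:

* **Search direction** is reverse-to-forward only; each reverse peak
  nominates exactly one candidate (its closest forward peak by $|d|$).
  If that candidate fails the gate the reverse peak stays unpaired — it
  does not fall back to the next-closest peak.
* **Ties.** Equal $|d|$ resolves to the smaller signed $d$ (i.e. the
  wrong-side candidate, which then discards the reverse peak), then to
  the leftmost forward start. When several reverse peaks claim the same
  forward peak, the smaller distance wins, then the leftmost forward
  peak, then the leftmost reverse peak; a forward peak anchors at most
  one cluster, and losing reverse peaks are not re-matched.
* **Degenerate adjacency.** A forward peak ending exactly at the reverse
  peak start has $d = -0$; admitting it would create an empty cluster
  span, so any wrong-side candidate — including this one — never forms a
  pair. The brute-force test oracle encodes the same rule.

Per-strand peaks must be non-overlapping within a strand (consensus
inputs are merged first); violating that is an error, not a silent
re-merge.

# Replicate consensus and kinetic classes

Per condition, clusters from the two replicates that overlap by at least
1 bp (no minimum fraction) are union-merged into consensus clusters;
overlap groups merge transitively. Each timepoint is tested against the
untreated control on normalized counts, and a cluster is *enriched* when
log2FC > 1 with p < 0.05 in the positive direction only. Kinetic classes
then follow from overlap between the per-timepoint enriched sets:
enriched at both timepoints (by $\ge$ 1 bp overlap) is persistent,
early-only is transient, late-only is late. Because cluster identity
across timepoints is defined by overlap, the promotion rule — a transient
cluster overlapping a late cluster becomes persistent, merged — is
exactly this overlap criterion; within each final class overlapping
clusters are merged, so the classes partition the enriched set. Clusters
enriched in neither contrast are reported in a side set, not dropped
silently.

# Normalization

Per library the raw spike factor is $f_i = \mathrm{RiP}_i /
\mathrm{RQC}_i$ (END-seq: on-target spike-in reads over total
quality-filtered reads) or the spike-in read fraction (DRIP). Factors are
rescaled by the minimum across the libraries of the experiment batch (so
$\min_i s_i = 1$ exactly), a library-size factor $\ell_i =
\mathrm{median}_j(\mathrm{RQC}_j)/\mathrm{RQC}_i$ is computed, and the
final factor is $s_i \ell_i$. Normalized counts are raw counts **divided**
by the final factor, so a library with higher spike recovery is deflated.
The direction of application is a convention; the synthetic generator
embeds the same final factor in every library's expected counts, so the
pipeline's normalization must invert exactly what was planted — a closed
loop that the tests verify. "Minimum within each replicate" was read as
the minimum across the libraries of one experiment batch. The factors are
exactly invariant under rescaling all RiP and RQC by a common constant.

# Moderated differential test

On $y = \log_2(\text{normalized count} + 0.5)$ a two-sample t-statistic
is formed with a moderated variance
$$\tilde s^2 = \frac{d_0 s_0^2 + d s^2}{d_0 + d}, \qquad
  s_0^2 = \mathrm{median}_\text{regions}(s^2),$$
with $s^2$ the pooled within-group variance on $d = n_A + n_B - 2$
degrees of freedom, and $t = \widehat{\mathrm{lfc}} / \sqrt{\tilde s^2
(1/n_A + 1/n_B)}$ referred to a t distribution on $d_0 + d$ degrees of
freedom. This is a median-variance moderation with fixed prior weight,
not an empirical-Bayes fit: it is an approximation chosen for
transparency and testability, and it degenerates correctly — $d_0 = 0$
reproduces the classical equal-variance t-test (verified against
`stats::t.test`), $d_0 = \infty$ fixes every region's variance at
$s_0^2$. If all regions have (near) zero variance, $s_0^2$ is floored at
$10^{-8}$ with a warning. Defaults: $d_0 = 4$, pseudocount 0.5. No
multiple-testing correction gates any decision (the procedure gates on
raw p-values by design).

The DRIP differential uses the p-only gate (p < 0.01, direction from the
log2FC sign); whether a fold-change gate also applied to hybrids was not
determinable, so it is off by default and configurable.

# RNase H filter and the seven categories

Regions pass the true-positive filter when IP counts exceed RNase-H
treated counts with log2FC > 1 and p < 0.05 — the only explicit gate
available, reused deliberately. The filter compares the untreated IP
libraries against the RNase H libraries. Failing regions are removed
before both contrasts. The early (5 min) and late (60 min) contrast
states (up / down / ns) then map onto: stable gain/loss (change that
persists), transient gain/loss (change at 5 min only), late gain/loss
(60 min only), no-change, with opposite-direction pairs reported as an
eighth *discordant* set that is never counted among the seven.

# Single-ended breaks

Per-strand consensus peaks farther than 150 bp from any opposite-strand
peak (overlap counts as distance 0) are solitary candidates. To remove
outliers, only peaks whose mean normalized count lies within
$[Q_1, Q_3]$ — linear-interpolation quantiles (R type 7), boundaries
inclusive, computed per strand — proceed to differential testing; with
fewer than four peaks on a strand the filter is skipped with a warning.
Which per-peak count enters the filter is a design choice here: the mean
normalized count across libraries.

# Overlap enrichment

The observed statistic is the number of query intervals overlapping at
least one feature by $\ge$ 1 bp (per-interval, not per-bp). Each of 100
randomizations redraws every interval's start uniformly within its own
chromosome, preserving lengths and per-chromosome counts; shuffled
intervals may overlap each other. Shuffles stay on the source chromosome
to preserve chromosome composition. The binomial success probability is
the moment estimate expected$/n$, clamped to
$[\tfrac{1}{2 n S}, 1 - \tfrac{1}{2 n S}]$ ($S$ shuffles) so degenerate
fixtures stay finite; the p-value is the upper tail when observed $\ge$
expected, the lower tail otherwise, and
$\mathrm{log2FC} = \log_2\frac{\text{obs} + 0.5}{\text{exp} + 0.5}$.
The fold change is the ratio of the observed count to the *mean* expected
count (not the mean of per-shuffle ratios), which is well-defined when
individual shuffles give zero overlaps. Because the tail is chosen by
direction, the statistic's size is close to (and can slightly exceed)
twice a one-tail level; the test suite measures it under uniform
placement.

Gene-feature annotation evaluates the peak midpoint against strand-aware
windows — promoter = 10 kbp upstream of the TSS plus the 5' UTR,
terminator = 3' UTR plus 10 kbp downstream of the TES, gene body = the
gene span — with priority promoter > terminator > gene body >
intergenic; every peak receives exactly one category. Metaprofiles are
reference-point only: `n_bins` equal bins across ±`half_window` around
each region midpoint, mean track value per bin, chromosome-edge positions
masked rather than zero-filled. Scaled gene-body metagenes are out of
scope.

# The synthetic study

The generator is the package's test bed and defines the study
conditions. On a 3 × 5 Mbp genome it plants, at mutually separated
positions (centres ≥ 3 kbp apart):

* 300 double-ended DSBs (100 per kinetic class), each a 300-bp reverse
  flank and 300-bp forward flank around a break with gap drawn from
  0–140 bp — after ±4 bp replicate jitter the realized gap stays below
  the 150-bp gate in every replicate;
* 50 single-ended DSBs (solitary peaks on a random strand, enriched at
  both timepoints) and 10 unenriched solitary noise peaks;
* 280 R-loop peaks (40 per category, widths 300–800 bp) plus 10% decoys
  whose RNase H counts stay at IP level;
* 300 gene models (5–20 kbp) for the annotation stage.

30% of persistent breaks are placed at stable-gain hybrid positions so
the enrichment stage has a planted colocalization to find; all other
class/feature combinations overlap only by chance.

Counts are negative binomial with shared dispersion 0.05, baseline mean
100 and planted |log2FC| = 2, with each library's expected value
multiplied by its own final scale factor (depth jittered ±30% around
10^6 reads, IP efficiency ±30%, spike ratio 1:1000), so normalization is
load-bearing, not decorative. RNase H libraries sit at baseline/10 for
true hybrid peaks. The truth table records every planted feature, class
and fold change; identical config and seed reproduce byte-identical
files (the manifest stores md5 checksums and no timestamps).

What the generator does **not** emulate: read-level artefacts (GC bias,
mappability, duplicates), peak-shape variation, correlated
replicate-to-replicate dispersion, blacklist regions, and genome-scale
feature density. Passing tests therefore demonstrate the correctness and
calibration of the procedures under a clean generative model — not
robustness to alignment pathologies. The dispersion default is a free
parameter; real replicate variance was not estimable from the source
material.

# Numerical choices and problem sizes

Quantiles are R type 7 everywhere. The pseudocount before log2 is 0.5.
The $s_0^2$ floor is $10^{-8}$. The binomial clamp is $1/(2 n S)$.
Deterministic output ordering is genome chromosome order, then start,
then end. Random placement uses rejection sampling with a feasibility
check (total footprint versus genome length) so infeasible configurations
fail fast instead of looping.

The shipped study sizes — 15 Mbp genome, ~670 planted features, 2,000
regions for calibration checks, 500 random pairing instances, 100
shuffles and 200 null runs for the enrichment statistic — were chosen so
the full test suite and the acceptance script each complete in a few
minutes on a single core while keeping Monte-Carlo error well inside the
asserted bands; they are stated here as the package's study design, and
scale up linearly if larger simulations are wanted.

# Limitations

* The moderated test approximates, but is not, limma's empirical-Bayes
  machinery; its fold changes agree with a limma linear fit (tested) but
  p-values are from the median-moderation model above.
* The pairing tie-break rules are a convention; real data with ties at
  identical distances are vanishingly rare, synthetic data can produce
  them, and the brute-force oracle pins the behaviour.
* The threshold peak caller is a stand-in sufficient for rectangular
  synthetic coverage; use a model-based caller for real data.
* Enrichment null models are uniform within chromosomes; no GC-,
  gene-density- or blacklist-matched nulls.
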