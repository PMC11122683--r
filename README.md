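# dsbrloop

Camptothecin traps topoisomerase I cleavage complexes (Top1cc) on DNA,
perturbs transcription and replication, and leaves two genomic footprints
that can be sequenced: DNA-RNA hybrids (R-loops, mapped by DRIP-seq) and
double-strand breaks (DSBs, mapped by END-seq, whose reads flank a break
strand-specifically — minus strand on the left, plus strand on the right).
`dsbrloop` implements the bespoke computational steps needed to turn those
assays into kinetic maps, and ships a seeded synthetic-data generator with
planted ground truth so the whole analysis runs — and is tested — end to
end without any external sequencing data. It is aimed at genomicists who
want the strand-pairing, normalization, and classification machinery as
reusable, verified functions.

## What it computes

**DSB clusters from strand-specific peaks.** For each reverse-strand peak
*r* the closest forward-strand peak *f* is found under the signed distance

d = f.start − r.end (f downstream), d = 0 (overlap), d < 0 (f on the wrong side)

and the pair is kept iff 0 ≤ d < 150 bp, defining a cluster
[r.start, f.end). Clusters present in both replicates (≥ 1 bp overlap) are
union-merged into consensus clusters per timepoint.

**Spike-in and library-size normalization.** Per library, the raw factor is
f = RiP/RQC (on-target spike-in reads over quality-filtered reads; for
DRIP, the spike-in read fraction), rescaled as s = f / min(f), combined
with ℓ = median(RQC)/RQC into the final factor s·ℓ, and counts are divided
by it.

**Moderated differential enrichment.** On y = log2(count + 0.5), a
two-sample t-test with variance moderated toward the median across regions:
s̃² = (d₀·s₀² + d·s²)/(d₀ + d), with s₀² = median(s²), d₀ = 4, referred to
t with d₀ + d degrees of freedom.

**Kinetic classification.** DSB clusters: *persistent* (enriched over
untreated at both 10 and 20 min, with |log2FC| > 1 and p < 0.05),
*transient* (10 min only), *late* (20 min only); transient clusters
overlapping late clusters are promoted to persistent and merged. R-loop
peaks: seven categories from the 5- and 60-min contrasts at p < 0.01 —
stable/transient/late gains and losses plus no-change (opposite-direction
changes are reported separately as discordant) — after an RNase H
true-positive filter (IP over RNase-H-treated control, log2FC > 1,
p < 0.05).

**Single-ended DSBs.** Solitary strand peaks > 150 bp from any
opposite-strand peak, with an inter-quartile count filter ([Q1, Q3],
linear-interpolation quantiles) before differential testing.

**Overlap enrichment.** Observed overlap counts versus the mean of 100
within-chromosome randomizations, p from a binomial tail with success
probability expected/n (clamped), log2FC = log2((obs+0.5)/(exp+0.5));
plus gene-feature annotation (±10 kbp promoter/terminator windows) and
reference-point metaprofiles.

## Worked example

```r
library(dsbrloop)

ds <- simulate_dataset(simulation_config(seed = 1))   # 3 x 5 Mbp genome,
                                                      # 300 planted deDSBs
libs <- subset(ds$libraries, assay == "ENDseq")
res  <- run_dsb_analysis(ds$peaks$endseq, ds$counts$endseq$regions,
                         ds$counts$endseq$counts, libs)
vapply(res$classes, length, 0L)
#> persistent  transient       late
#>         98        101        101
head(res$factors, 3)
#>        library_id          raw    spike   libsize     final
#> 1  endseq_NT_rep1 0.0011417899 1.397354 1.2122149 1.6938927
#> 2 endseq_T10_rep1 0.0008285566 1.014010 0.8239325 0.8354759
#> 3 endseq_T20_rep1 0.0008832426 1.080936 1.1292600 1.2206582
```

The 300 planted breaks (100 per class) come back as 98/101/101 clusters:
one persistent break missed a gate in one contrast and two planted
persistent regions were called in a neighbouring class. Scale factors show
the planted library perturbations (spike recovery and depth) that the
normalization undoes. The DRIP branch is symmetric:

```r
drip <- subset(ds$libraries, assay == "DRIP")
rl <- run_rloop_analysis(ds$peaks$drip, ds$counts$drip$regions,
                         ds$counts$drip$counts, drip)
table(rl$universe$category)
#>    stable_gain    stable_loss transient_gain transient_loss      late_gain
#>             40             37             40             41             39
#>      late_loss      no_change     discordant
#>             38             44              1
```

## The analysis workflow

The numbered scripts under `analysis/` run the full synthetic study and
narrate what they find, writing tables and BEDs under `results/`:

```sh
Rscript analysis/01_simulate.R        # dataset + truth under results/synthetic/
Rscript analysis/02_call_dsb.R        # pairing -> consensus -> classes -> seDSB
Rscript analysis/03_classify_rloops.R # RNase H filter -> seven categories
Rscript analysis/04_enrichment.R      # DSB classes over R-loop categories
```

Stage 4 recovers the planted colocalization of persistent breaks with
stable hybrid gains (observed 28 overlaps vs 0.35 expected, log2FC 5.1,
p ≈ 6e-45 in the run above) and annotates clusters by gene feature.

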