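# grchip

Analysis of glucocorticoid receptor (GR) ChIP-seq in brain tissue, rebuilt as
a tested R package plus a numbered analysis workflow. GR is a ligand-activated
transcription factor; where it binds in the genome is set by chromatin
accessibility and by the DNA elements beneath each binding site — a full
palindromic glucocorticoid response element (GRE, consensus
`ACAnnnTGT(T/C)CT`), a GRE half-site (`TGTYCT`), flanking half-sites for
collaborating factors such as NF-1 (`TTGGCA`) and bHLH/E-box factors
(`CANATGG`, NeuroD1/Olig2-like), or the distinct negative GRE
(`CTCC(N)0–2GGAGA`) linked to repression. The package implements the full
chain used to characterise such data:

- **Tag processing** — deduplication on (chrom, 5′ position, strand),
  3′ extension to 150 bp, tags-per-10-million depth normalisation, simple
  tandem-repeat masking, binned density tracks.
- **Hotspot peak calling** — windowed upper-tail binomial enrichment of ChIP
  over a depth-ratio-scaled local input expectation (200-bp windows, 50-bp
  step, 25-kb local background), BH q < 0.01, window merging, summit
  detection; replicate-concordant regions, top-20% selection by tag density,
  cross-group pooling of non-duplicated positions.
- **Differential binding** — raw midpoint counting at peaks, median-of-ratios
  size factors, method-of-moments NB dispersions with a fitted mean–dispersion
  trend, a conditional negative-binomial exact test (the probability of group
  splits of the pooled count as or less likely than the one observed), BH
  adjustment, and log2 intensity scatter/MA concordance between groups.
- **Annotation** — nearest-TSS distances signed by gene orientation, exclusive
  summit categories with a −5 kb/+100 bp promoter definition, and the
  gene-proximal subset (gene body or extended promoter).
- **Motif architecture** — IUPAC consensus compilation (including
  variable-spacer motifs), exhaustive both-strand scanning with palindrome
  deduplication and soft-mask awareness, per-peak architecture flags (a full
  GRE implies its half-site), full-GRE partition frequencies, ±1 kb positional
  histograms, strength stratification (top vs bottom third by density),
  composite-class tables, nGRE centrality analysis, and a k-mer enrichment
  stand-in for de novo discovery.
- **Synthetic data with planted truth** — a motif-free background genome
  (verified by exhaustive scan), exact-count planting of motif architectures,
  and a strand-shift read simulator (two conditions × two replicates of ChIP
  plus matched inputs, null between conditions), so every stage is testable
  without external downloads.

## Worked example

The numbered scripts under `analysis/` run the whole study on simulated data
(about two minutes total) and write their tables under `results/analysis/`:

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_call_peaks.R
Rscript analysis/03_differential_binding.R
Rscript analysis/04_annotate_peaks.R
Rscript analysis/05_motif_architecture.R
Rscript analysis/06_ngre_analysis.R
```

Output from a run of stages 2–3 (200 planted sites, 3 Mb genome,
~290k tags/sample):

```
c1: 200/201 replicate peaks, 200 concordant (100% of planted sites recovered), top 20% = 40
c2: 200/200 replicate peaks, 200 concordant (100% of planted sites recovered), top 20% = 40
pooled non-duplicated positions: 200 (200 in both groups)
size factors: 1.009 1 0.997 1.001
200 peaks tested; 0 at BH-adjusted p < 0.05 (null design)
between-group intensity concordance: Pearson r = 0.9638
```

Both replicates in each condition recover every planted site; because the
simulation has no true between-condition difference, the NB exact test finds
no significant peaks and the two conditions' log2 peak intensities are highly
concordant — the expected behaviour for GR binding measured with and without
an acute stress context. Stage 5 then reports, for the same peaks, the motif
frequencies in the top vs bottom density thirds (e.g. full GRE 0.89 vs 0.06,
NF-1 0.86 vs 0.23), showing that composite architectures concentrate in
stronger peaks, and stage 6 shows that at peaks containing an nGRE a
conventional GRE form usually sits closer to the summit.

Equivalent programmatic use:

```r
library(grchip)
cfg <- default_composition()              # 7298 sites, reported class mix
genome <- generate_background_genome(1e7, seed = 1)
ps <- plant_sites(genome, cfg, seed = 2)
hits <- scan_peaks(ps$genome,
                   data.frame(peak_id = ps$truth$site_id,
                              chrom = ps$truth$chrom,
                              summit = ps$truth$center))
arch <- classify_architecture(hits, ps$truth$site_id)
mean(arch$has_full_gre)                   # 0.4523
```

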