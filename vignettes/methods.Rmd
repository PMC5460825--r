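---
title: "Methods: synthetic GR ChIP-seq analysis from tags to motif architecture"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: synthetic GR ChIP-seq analysis from tags to motif architecture}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette is the package's own account of what it computes and why the
defaults are what they are. The pipeline characterises glucocorticoid
receptor (GR) binding measured by ChIP-seq in a replicated two-condition
design: preprocessing of aligned tags, enrichment ("hotspot") detection
against matched input, replicate concordance, a negative-binomial test for
between-condition intensity differences, nearest-TSS annotation, and a
consensus-motif analysis of the sequence beneath each binding site. A
synthetic-data module plants binding sites with known motif architecture so
that every downstream claim can be checked against ground truth.

## Tag model and preprocessing

Aligned tags arrive as stranded BED6 intervals, 0-based half-open throughout
(conversions happen only in parsers). Duplicates are removed first, keyed on
(chromosome, 5′ coordinate, strand) — the 5′ end is the sequenced position,
so this is the natural PCR-duplicate key; the key is applied *before*
extension because extension is deterministic given the 5′ end. Tags are then
extended to 150 bp in their 3′ direction, approximating the sonicated
fragment each read came from; at chromosome boundaries the interval is
clipped. Depth normalisation is tags-per-10-million (`1e7/total`). Density
tracks bin the genome at 50 bp and count each extended tag once, at its
midpoint bin: for 200-bp window statistics the midpoint rule is
indistinguishable from overlap-weighting and far cheaper; overlap weighting
is not the default for that reason.

Simple tandem repeats (unit ≤ 6 bp, run ≥ 24 bp, detected by backreference
regex per unit length and merged) can be masked: peak-calling windows
overlapping a masked interval by ≥ 1 bp are excluded, and masked bases are
lowercased so the motif scanner never matches them. Abutting intervals do
not overlap under the half-open convention.

## Hotspot calling, concordance, ranking

The caller tests sliding windows (200 bp wide, 50-bp step) for ChIP
enrichment over an expected count, which is the maximum of three quantities:
the input count in a 25-kb window around the same position scaled by window
size and by the ChIP/input depth ratio (local chromatin bias), the
genome-average ChIP expectation (global floor), and a pseudocount of 1
(numerical floor where input is sparse). Window significance is the
upper-tail binomial probability of the observed count given total ChIP depth
and the expected fraction; Benjamini–Hochberg control across all windows at
q < 0.01 defines significant windows, which merge when closer than 150 bp.
The summit is the centre of the maximum-density 50-bp bin (leftmost on
ties). The internals of the original in-house hotspot approach are not
published; this windowed-binomial construction is a reimplementation of its
idea with every parameter exposed.

Replicate concordance keeps regions where peaks from both replicates overlap
by ≥ 1 bp, reporting the union interval, the mean of the two replicates'
best-window densities (tags/10M), and the denser constituent's summit. "Tag
density" for ranking is the maximum 200-bp-window count within the peak
scaled to tags-per-10M; the top 20% per condition (ties broken by ascending
p, then coordinate) are carried forward, and the two conditions' surviving
regions are pooled with overlaps merged into single non-duplicated records
flagged by provenance.

## Differential binding

Counting at pooled peaks is raw and integer: a tag counts for a peak iff its
midpoint lies in `[start, end)`. Size factors are median-of-ratios: per
sample, the median over all-positive peaks of the ratio to the peak's
geometric mean. Dispersion is estimated per peak by method of moments — the
pooled within-group variance of normalised counts minus the expected shot
noise, divided by the squared base mean — and a mean–dispersion trend
`a0 + a1/mean` is fitted across peaks by least squares.

Two details matter at the design size of two replicates per group. First,
the trend is fitted on *all* per-peak estimates, including negative ones;
restricting to positive estimates selects upward noise and biases the trend
high. Second, the dispersion used for testing is the trend value at the
peak's base mean (`sharing = "trend"`), not the per-peak maximum of estimate
and trend: with two replicates the per-peak moment estimate has standard
deviation of order 1/mean, so a per-peak maximum inflates the NB variance by
a factor independent of sequencing depth and makes null p-values strongly
conservative — measured here as a null p median around 0.7 where 0.5 is
expected. The conservative maximum remains available (`sharing = "max"`) for
users who prefer it on real data with outlier peaks; the package default is
the calibrated choice. Values are floored at 1e-8.

The test itself is a conditional NB exact test on the split of the pooled
count K between groups: under the null, group sums are NB with means
proportional to summed size factors and variances from the estimated
dispersion (moment-matched NB size); the two-sided p-value sums the
probabilities of all splits as or less likely than the observed one,
normalised over all K+1 splits. It reduces to a conditional binomial test as
dispersion → 0, returns p = 1 for perfectly balanced splits and for
zero-count peaks, and is computed by full enumeration (probabilities in log
space, normalised after shifting by the maximum). Log2 fold changes use
normalised group means with a 0.5 pseudocount; BH adjustment uses
`stats::p.adjust`. Intensity concordance tables report, per peak,
`x = log2(dA + 0.5)`, `y = log2(dB + 0.5)`, `M = y − x`, `A = (x + y)/2`,
plus the Pearson correlation of x and y.

## Annotation

The TSS is `txStart` for plus-strand genes and `txEnd` for minus-strand
genes; distances are signed relative to gene orientation so negative always
means upstream, and ties between equidistant genes go to the
lexicographically smaller gene id. Each peak receives one exclusive category
evaluated at its summit, with precedence promoter > 5′UTR > exon > intron >
3′UTR > intergenic; the promoter is distance ∈ [−5000, +100] bp. Synthetic
gene models carry no CDS, so the strand-aware first and last exons stand in
for the UTR-containing segments. The gene-proximal subset is every
non-intergenic peak — equivalently, summit in a gene body or within 5 kb
upstream of a TSS.

## Motif layer

Motifs are IUPAC consensus strings; gapped specifications expand to one
pattern per spacer length (the negative GRE `CTCC(N)0–2GGAGA` becomes three
exact patterns). The default library: full GRE `ACANNNTGTYCT`; GRE half-site
`TGTYCT` (the 3′ arm of the palindrome — no separate half-site string is in
common use); NF-1 half-site `TTGGCA` (the TTGGC-containing half of the
canonical full site `TTGGC(N5)GCCAA`); bHLH `CANATGG` (NeuroD1/Olig2-like,
with `CAGCTG` selectable); nGRE as above, exact matches only. All are
overridable.

Scanning enumerates every position × strand whose bases satisfy the pattern
(regex over character classes, lookahead for overlapping matches); a match
whose interval is hit on both strands (palindromic instance) is reported
once, on the plus strand. Lowercase bases never match. The frequency-counting
window is summit ± 100 bp and the histogram window summit ± 1000 bp; neither
is dictated by the underlying protocol, so both are arguments. The scanner is
verified in the tests against two independent oracles: a brute-force regex
scanner written in the test code, and `Biostrings::matchPattern` with
`fixed = FALSE`.

Architecture flags are per-class presence/absence in the counting window; a
full-GRE hit sets the half-site flag because the palindrome's 3′ arm *is* a
half-site — the implication is structural, not a convention. Composite labels
partition peaks into GRE/H alone, GRE/H+NF1, GRE/H+bHLH, GRE/H+NF1+bHLH,
non-GRE motifs only, and none. Strength stratification sorts peaks by
descending density and compares per-class frequencies between the top and
bottom `floor(n/3)`; half-site hits nested inside a full-GRE hit are not
double-counted for frequencies but are retained for the implication flag.
The nGRE analysis, restricted to peaks with an nGRE hit in the wide window,
compares the most central nGRE with the most central GRE-form hit per peak
and summarises how many nGRE peaks lack any GRE form.

The k-mer enrichment pass is a deliberately simple stand-in for de novo
discovery: per width (6–16 bp), sequences containing each
reverse-complement-canonicalised k-mer are counted in foreground and
background and ranked by hypergeometric upper-tail p with BH adjustment per
width. The default background resamples each foreground sequence from its
own first-order Markov (dinucleotide) model — dinucleotide frequencies are
preserved in expectation rather than exactly, which suffices for a ranking
stand-in. Exact k-mer counting dilutes degenerate motifs across their
concrete realisations, so consensus scanning, not this pass, is the primary
motif instrument.

## Synthetic data: what it emulates, and what it does not

The generator builds a background genome by sampling bases at a target GC
fraction (default 0.42, a typical mammalian genome-wide value) and then
resampling any window that matches a library motif on either strand until an
exhaustive scan finds zero hits. This generate-then-repair loop replaces
per-window rejection during generation: the guarantee that matters — the
final verified motif-free scan — is identical, and repairing the handful of
hits in a realised sequence is orders of magnitude cheaper than per-window
rejection while generating. The same repair machinery runs after planting,
because writing a concrete motif instance into background can create
unintended matches straddling the insertion boundary (for example, background
`ACA` three bases upstream of a planted `TGTYCT` completes a full GRE); any
hit not implied by the site's intended classes is destroyed by resampling
the non-instance bases it spans (or re-realising the instance's degenerate
positions when the hit lies wholly inside planted bases). Planting is
therefore *exact*: scanned per-class peak frequencies equal the configured
counts, which is what makes composition recovery a sharp test.

Sites are spaced ≥ `min_spacing` apart (default 1000 bp; 2000 bp in the
read-level studies so neighbouring pileups cannot merge), away from
chromosome ends. Instance offsets from the site centre are truncated normal
(SD 15 bp for GRE forms, 60 bp for NF-1/bHLH/nGRE — the non-GRE motifs are
positionally looser in real binding sites), constrained inside the ± 100 bp
counting half-width and non-overlapping within a site. The default
composition (`inst/extdata/default_composition.yaml`, loaded by
`default_composition()`) encodes the reported hippocampal accounting: 7298
sites; 3301 with a full GRE; 3262 with a half-site only (so 89.9% carry some
GRE form and 735 neither); 3985 (54.6%) with NF-1; 1248 (17.1%) with bHLH;
126 with an nGRE, 6 of which lack any GRE form. The de-novo-discovery
"percentage targets" reported alongside those numbers (49% full GRE, 61.2%
half-site) describe discovered PWM models rather than consensus-match
counts and are arithmetically incompatible with the accounting above; the
config follows the consensus accounting because consensus scanning is what
this package does.

Enrichment weight is 1 + the sum of planted class weights (defaults: full
GRE 1.5, half-site/NF-1/bHLH 0.75, nGRE 0.25), so composite sites are
stronger — the generative form of the observation that composite motifs
concentrate in stronger peaks, and the reason strength stratification has a
planted direction to recover. Reads: per site and ChIP sample, fragment
count ~ Poisson(depth × weight × condition multiplier) with depth 100 per
unit weight; fragment centres ~ Normal(centre, 50 bp); each fragment yields
one 36-bp read whose 5′ end sits 75 bp upstream (plus) or downstream
(minus) of the centre, the classic strand shift that extension to 150 bp
recentres. Background reads are uniform at 0.08 tags/bp, and input samples
are background-only; at the default 10 Mb/800-site study scale this gives
roughly a million tags per sample. The condition multiplier defaults to 1.0
— the between-condition null, matching the finding that an acute stress
context does not redistribute GR binding; replicated simulations under this
null are expected to produce zero BH-significant peaks and high intensity
concordance, which is exactly what the acceptance tests check. No
fragment-size distribution for the underlying chromatin preparation is
published, so the dispersion and shift defaults are asserted, not derived.

Not emulated: sequencing errors, mappability structure, GC bias, diploid
variation, PCR duplication, chromatin-accessibility covariates, and real
genomic repeat structure. Passing tests therefore demonstrate the pipeline's
internal correctness and calibration under a clean generative model, not
robustness to every artefact of real libraries.

## Numerical choices and degenerate inputs

- Ties: summit ties go leftmost; ranking ties break by ascending p then
  coordinate; equidistant TSS ties by gene id.
- Empty inputs: empty tag sets give all-zero tracks; an empty ChIP track is
  an error; an empty input track falls back to the genome-average
  expectation with a warning; zero-count peaks get p = 1, fold change 0.
- The exact test's enumeration tolerates ties in outcome probabilities with
  a 1 + 1e-7 relative slack, and log-space shifting prevents underflow at
  large pooled counts.
- Calibration studies of the exact test are run at the count level via
  `simulate_site_counts()` (the generator's Poisson site-count model): at
  synthetic per-site depths, read-level simulation plus deduplication
  removes coincidental 5′-position collisions, leaving counts sub-Poisson
  and the conditional test conservative — a property of duplicate removal on
  duplicate-free libraries, not of the test. The study uses deep counts
  (mean 2000 per unit weight) so that the exact test's discreteness — its
  atom at p = 1, of size about sqrt(2/πK) — stays below 1% and cannot
  confound a continuous-uniformity check at 2000 peaks.
- All randomness flows from one seed per entry point, split deterministically
  per sample; identical seeds give byte-identical outputs, and the RNG state
  of the calling session is restored afterwards.

## Known limitations

The hotspot internals are a reconstruction, not the original code; absolute
peak boundaries and p-values are not comparable to other callers, though
recovery and calibration are tested. The NB exact test enumerates all splits
and is not intended for pooled counts beyond ~10^6. Consensus scanning has no
match-quality score — a motif either satisfies the IUPAC pattern or it does
not — so "similarity percentage" style statements about discovered models are
out of scope, as is full de novo motif discovery. UTR categories in
synthetic annotation are exon-boundary surrogates. The k-mer stand-in should
not be read as a motif-discovery result.
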