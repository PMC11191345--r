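---
title: "Methods: how sexscan decides whether a genome has sex-specific regions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: how sexscan decides whether a genome has sex-specific regions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sexscan)
```

## The question and the evidence model

In a gonochoristic species, strong sexual dimorphism invites the hypothesis
of genetic sex determination: a Y (or W) chromosome, or smaller
sex-specific regions. But sex-biased *transcription* is weak evidence for
sex-specific *DNA* — spermatogenesis genes can sit on perfectly ordinary
autosomes. `sexscan` therefore treats the question as three separable
measurements on one assembly, each with its own failure modes, and only
calls an architecture when the DNA-level channels agree.

### Expression channel

Counts are converted to TPM (`compute_tpm()`), so that library size and
transcript length cancel; each sample's TPM column sums to $10^6$. The
per-gene effect statistic is the pseudocounted mean-TPM ratio

$$\mathrm{log2FC} = \log_2\frac{\overline{\mathrm{TPM}}_M + 0.1}
{\overline{\mathrm{TPM}}_F + 0.1},$$

with the arithmetic mean over each sex's samples. The pseudocount of 0.1
makes the statistic finite for genes silent in one sex while barely
perturbing expressed genes; the arithmetic (rather than geometric) mean was
chosen as the plainest estimator at the 3–4 replicates the design
anticipates, where a geometric mean is fragile to zeros.

Differential expression is deliberately pluggable. The built-in test
(`de_test()`) is Welch's $t$ on $\log_2(\mathrm{TPM}+1)$ with
Benjamini–Hochberg adjustment and a significance gate at FDR < 0.05;
a table from any external tool (e.g. a negative-binomial model) can be
ingested with `read_de_table()` instead. Downstream stages consume only
(log2FC, FDR), so the choice of DE engine does not propagate further. The
strongly biased sets (`select_biased()`) require *both* significance and a
fold change above 10× — the fold gate is what restricts the sets to genes
with near-exclusive expression in one sex.

Window enrichment (`make_windows()`, `assign_genes()`, `window_fisher()`)
slides 200 kbp windows at 100 kbp steps, emitting a window at every step
start below the scaffold length and truncating at the scaffold end
(trailing short windows are kept and tested like any other — excluding them
would silently untest scaffold ends). A gene belongs to every window it
overlaps by ≥ 1 bp, the convention of the standard interval toolkits.
Each window's 2×2 table is tested one-sided (enrichment only) against the
*de-duplicated* genome-wide gene universe: a gene spanning three windows
counts in each window it touches but only once in the "outside" margin, so
the table margins always sum to the universe size. BH correction runs over
all windows of one sex's analysis — male and female scans are corrected
separately, since they are separate hypothesis families. Windows with zero
genes receive $p = 1$ and stay in the BH family; this is deterministic and
slightly conservative. Enriched windows (Q < 0.01) merge into maximal
regions by interval union.

### Coverage channel

Each sample's binned depth (10 kbp bins by default) is divided by its own
median over *all* bins, zero-depth bins included — the median is the right
anchor because most of any plausible genome is autosomal, and it makes the
statistic invariant to per-sample sequencing depth. Per-bin sex means are
then classified by bands:

| label | male mean | female mean |
|---|---|---|
| `autosomal` | 0.8–1.2 | 0.8–1.2 |
| `hemizygous_M` (X-like) | 0.35–0.65 | 0.8–1.2 |
| `specific_M` (Y-like) | 0.35–1.2 | ≤ 0.1 |
| mirrored for F | | |

The half band of ±0.15 around 0.5 and the diploid band of ±0.2 around 1
absorb Poisson counting noise at the 15–20× depths the method targets
(at 20× over a 10 kbp bin averaged across 3–4 samples, the standard error
of a normalized bin mean is ~0.02, so the bands are many standard errors
wide); they are exposed as arguments, not constants. Anything outside every
band is `ambiguous` rather than silently forced into a class. One caveat
follows from the median anchor: if sex-linked sequence makes up half or
more of the assembly, the median no longer sits on autosomal depth and
classification degrades — the generator's defaults keep sex scaffolds a
minority, as in any realistic assembly.

`coverage_of_regions()` closes the loop between channels: it reports the
per-sex mean coverage of the expression-enriched regions, implementing the
key negative control — if "male-biased" regions have ordinary diploid
coverage in females, their DNA is not male-specific.

### k-mer channel (P_VSC_UK)

For each contig, with $k = 15$:

* **SC** — the contig's canonical k-mers occurring exactly once in the
  whole assembly (repeats carry no locational information);
* **VSC** — SC k-mers also present in the *trusted* read k-mers of the sex
  expected to carry the contig (male for the XY direction); this validation
  step removes assembly-error k-mers that no read supports;
* **VSC_UK** — VSC k-mers absent from the opposite sex's trusted k-mers;
* $P_{VSC\_UK} = 100 \cdot |VSC\_UK| / |VSC|$.

Trusted means count ≥ 2 in the pooled per-sex table: at ~20× depth a
genuine single-copy k-mer is seen ~10 times per sex, so singletons are
overwhelmingly sequencing errors; the cutoff is configurable because the
right value scales with depth. Canonical form is the lexicographic minimum
of a k-mer and its reverse complement (reads are unstranded), and $k$ must
be odd so no k-mer is its own reverse complement. k-mers are held as 2-bit
packed integer codes; the implementation stores codes in doubles, which are
exact to $2^{53}$, giving a capacity bound of $k \le 26$ — comfortably
above the $k = 15$ the method uses. Windows containing non-ACGT characters
are skipped entirely.

The scan runs in both directions: XY (carrier = male reads; a Y candidate
has $P_{VSC\_UK} \to 100$) and ZW (mirrored). Flagging requires
$P_{VSC\_UK} > 80$ — high, because even true Y contigs lose a few percent
to shared repeats and read noise, while autosomes sit near 0 — plus a
≥ 1,000 bp length filter and ≥ 20 VSC k-mers (a percentage on a handful of
k-mers is noise; this complements the length filter for gene-poor short
contigs). Contigs with no VSC k-mers report a missing percentage rather
than 0 or 100, and can never be flagged.

A dedicated diagnostic (`bidirectional_stats()`) watches for contigs near
50% in *both* directions. That pattern cannot come from sex linkage — a
contig cannot be specific to both sexes — but arises naturally from
individual variability: if each sex's read pool contains private haplotype
sequence, both directions inflate symmetrically. When more than 10% of
contigs fall in the 40–60% band in both directions the anomaly flag is
raised, and the verdict logic discounts any "flag" whose opposite-direction
value is also elevated.

### Verdict

`call_verdict()` is a pure function of the stage outputs. An XY call needs
screened XY-direction k-mer flags and/or coverage support (male-specific
*and* male-hemizygous bins together); ZW is mirrored. The negative call
`no_sex_specific_regions` is only available when both DNA channels actually
ran and neither found anything — and expression enrichment, however strong,
cannot override it. If either channel is skipped, the pipeline degrades to
`inconclusive` or a candidate call, never a confident negative.

## What the generator simulates — and what it does not

`sim_config()` declares a study: random-uniform nucleotide scaffolds;
under XY an X (1 male copy / 2 female) and a Y (1/0), under ZW the mirror;
non-overlapping genes of 300–3,000 bp (the spread exercises TPM length
normalization); NB expression counts with a log-normal baseline
(meanlog = log 100, sdlog = 1) and a 16× multiplier for biased genes;
Poisson per-bin coverage proportional to copy number; per-sex k-mer tables
with Poisson counts (zeros raised to 1 so present k-mers are never lost)
plus a configurable mass of uniform-random singleton error k-mers.

Defaults are the study conditions the pipeline targets: 4 male / 3 female
replicates, ~20× depth, 15-mers, 16× biased-gene effect against the 10×
downstream filter, and 3% of genes biased per sex — biased sets of a few
percent of the transcriptome, kept symmetric between the sexes so that the
biased minority does not shift TPM composition between sexes (with
markedly asymmetric biased mass, TPM renormalization deflates the apparent
fold change of truly biased genes; the clustered-bias scenario in the
acceptance script uses 10% per sex, still symmetric). Biased genes land on
configured cluster scaffolds with probability 0.9 — enough to concentrate
enrichment without making recovery trivial — and are drawn only from
scaffolds present in both sexes, so expression bias stays orthogonal to
copy number. Error k-mers are modeled as novel uniform k-mers with count 1:
that is exactly the population the trusted-k-mer filter exists to remove,
and read-level error simulation (positional errors, quality profiles)
would add realism the k-mer-set method never sees.

The generator deliberately omits: repeats and low-complexity sequence
(real assemblies have non-unique k-mers well above our junction-duplicate
rate), heterozygosity within sexes (except as injected private k-mers in
dedicated tests), GC/mappability coverage waves, partial sex linkage and
recombining pseudoautosomal regions, and any read-level artifacts. Passing
parameter recovery therefore demonstrates that the *statistics and logic*
are correct under their stated model, not that real data will be as clean; on real data the bands, trusted cutoff, and anomaly
fraction are the knobs to revisit first.

Determinism is a contract: a `sim_config` (including its seed) fixes every
output byte-for-byte. Stage seeds are derived from the config seed, so
stages can be rerun independently and still agree.

## Numerical and interface choices

* Fisher one-sided $p$ is the exact hypergeometric upper tail
  ($\texttt{phyper}(x-1, K, N-K, n, \mathrm{lower.tail=FALSE})$); the test
  suite cross-checks it against direct binomial-coefficient enumeration,
  and BH against the brute-force step-up definition.
* Degenerate inputs are explicit: all-zero count columns and zero-median
  coverage samples are errors (their normalizations are undefined);
  constant genes get $p = 1$; empty biased sets give $p = 1$ everywhere;
  empty region lists give empty tables, not errors.
* PCA (`pca_profiles()`) is mean-centered with a deterministic sign
  convention (the largest-magnitude loading is made positive), so repeated
  runs and platforms agree.
* All genomic coordinates are 0-based half-open throughout; BED output is
  native, GFF3 input is converted on read.
* The package's interface is its functions, composable with the pipe;
  a thin Rscript wrapper (`inst/scripts/sexscan.R`) covers the
  simulate/run-all entry points for shell use. Report bundles are
  plain-text (FASTA/BED6/TSV/JSON) with `.` for missing values and stable
  column order, and are byte-identical across reruns.

## Problem sizes used in the tests

The shipped validation uses desk-scale studies chosen to keep the full
suite in minutes while leaving each statistic well-measured: oracle
equivalence on 500 random Fisher tables, 1,000 p-vectors, 100 random
annotation/grid pairs, and a ~90 kbp three-contig assembly at $k = 15$;
XY parameter recovery on 20 replicates of the default six-scaffold
(~1.2 Mbp) genome; DE calibration on 20 replicates of 2,000 genes; and the
no-sex-chromosome scenario on six scaffolds with biased genes clustered on
two. The acceptance script reruns all of these from scratch under a single
user-supplied seed.

## Known limitations

* The built-in DE test is a simple Welch-$t$ stand-in intended for
  synthetic and exploratory use; for real RNA-Seq, fit a count model in a
  dedicated tool and ingest its table.
* P_VSC_UK inherits the assembly's quality: collapsed repeats shrink SC,
  and a missing Y assembly yields nothing to flag (the coverage channel is
  then the only DNA evidence).
* The coverage classifier assumes sex-linked sequence is a minority of the
  assembly (median anchoring) and that depth is roughly uniform; strong
  GC waves would widen the empirical bands.
* The verdict is qualitative by design. It reports candidate architecture
  and the evidence counts; it does not estimate the age, size, or gene
  content of a sex-linked region.
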