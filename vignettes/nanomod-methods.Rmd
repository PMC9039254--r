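---
title: "Calling RNA modifications from nanopore error profiles: models and methods"
author: "nanomod"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling RNA modifications from nanopore error profiles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nanomod)
library(GenomicRanges)
```

## The problem

Nanopore sequencing of native RNA (dRNA-seq) reads the RNA molecule itself,
so chemically modified nucleotides (m6A and others) perturb the signal and
surface as *systematic base-calling errors* at and around the modified
position. Sequencing a cDNA copy of the same molecule (dcDNA-seq) erases
that signal. This package implements the downstream statistical pipeline
for such experiments on a transcript-annotated genome: read-level QC and
classification, per-base error profiling, modification-site calling
against a background error model, differential modification between two
conditions with biological replicates, and transcript-level summaries —
together with a read simulator that reproduces the statistical structure
the analysis assumes, so that every stage can be validated against a known
truth at desk scale.

## Read QC and classification

Reads are classified per read *name* using SAM flags and the
supplementary-alignment (`SA`) tag:

* **unmapped** — the primary record carries flag 0x4;
* **chimeric** — any record is supplementary (0x800), or the primary
  carries an `SA` tag; chimeras are alignments split across distinct loci
  and are a hallmark of failed second-strand synthesis in direct-cDNA
  libraries (observed at 15–20% there);
* **other** — read names with only secondary records, or a primary CIGAR
  whose consumed query length disagrees with the stored sequence; this
  category is not standardized elsewhere, so we define it explicitly;
* **mapped** — everything else.

The pass/fail filter mirrors the base-caller convention: a read passes
when its mean quality is **at least 7** and its length **strictly
exceeds 200 bases** ("&gt;200" is read literally, so a 200-base read
fails). Mean read quality is the standard per-read Q,
$-10\log_{10}\left(\overline{10^{-q_i/10}}\right)$ — per-base Phred
scores converted to error probabilities, averaged, and converted back. We
round this value at the sixth decimal so that constant-quality reads sit
exactly on their nominal score; the boundary at Q7 is inclusive.

Percent identity of a mapped record is
$100\,( \text{aligned columns} - \mathrm{NM}) / \text{aligned columns}$,
with aligned columns counted from the CIGAR (M/=/X/I/D). At the default
simulated background error of 12% per base this lands at the ~88%
identity typical of nanopore RNA reads.

## The error-at-specific-base (ESB) model

For every reference position in the regions of interest the pileup
records `coverage` (primary, QC-passed, non-chimeric reads aligned across
the position) and `n_error`, where a read contributes **at most one
error** per position: a substitution at the position, a deletion spanning
it, or an insertion immediately following it. Insertions are attributed
to the preceding reference base (left attribution); a deletion counts at
every position it spans, once per read. The ESB is `n_error / coverage`.

A site is tested against a background error model by a one-sided Fisher
exact test on

$$\begin{pmatrix} n_{err} & cov - n_{err} \\ e_0 & n_0 - e_0 \end{pmatrix}$$

with the alternative that the site's error rate *exceeds* the background
— one-sided because modification only elevates error. The reported odds
ratio is the Haldane-corrected cross-product
$\frac{(a+\tfrac12)(d+\tfrac12)}{(b+\tfrac12)(c+\tfrac12)}$, finite even
with empty cells. Three background modes supply $(e_0, n_0)$:

* **constant** — a single rate $p_0$ (default 0.12) as a pseudo-sample
  $(\mathrm{round}(p_0 n_0), n_0)$ with $n_0 = 1000$. The pseudo-count
  size bounds the evidence the model-based null can contribute; 1000 makes
  the background roughly as informative as a deeply covered site.
* **context** — a 5-mer table of rates (with a `default` fallback),
  acknowledging that nanopore error is sequence-context dependent.
* **paired control** — error counts at the same site from a matched
  control pileup (e.g. IVT or cDNA); recommended when available since it
  is a direct ESB-vs-ESB comparison and needs no parametric null.

Sites below `min_coverage` (default 20 reads) are excluded and reported;
low-coverage sites cannot reach the calling thresholds anyway, and the
floor keeps the test out of the regime where the hypergeometric is
dominated by a handful of reads. P-values are Benjamini–Hochberg adjusted
over **all tested sites in the run** (a global family; per-transcript
adjustment would make thresholds depend on transcript size). The
headline profiling cutoffs are odds ratio $\ge 3$ and adjusted
$p < 10^{-50}$; that p-threshold presumes production sequencing depth
(tens of thousands of reads), so at simulation scale (coverage ~200) the
package's validation uses $10^{-6}$ as the desk-scale surrogate — same
estimator, same geometry, attainable evidence.

## Differential modification across replicates

Two conditions with $K$ biological replicates are compared per site by
the Cochran–Mantel–Haenszel test over $K$ replicate-paired 2×2
error/non-error tables (replicate $k$ of A versus replicate $k$ of B;
index pairing is a fixed convention, and the statistic is invariant to
stratum order):

$$X^2 = \frac{\left(\left|\sum_k (a_k - E[a_k])\right| - c\right)^2}
             {\sum_k \mathrm{Var}(a_k)},\qquad
E,\ \mathrm{Var}\ \text{hypergeometric per stratum},$$

referred to $\chi^2_1$. The continuity correction $c = \tfrac12$ is
applied only when $\left|\sum (a_k - E_k)\right| \ge \tfrac12$, matching
the behaviour of standard implementations (`stats::mantelhaen.test`,
which the test suite uses as the independent oracle). Strata with a zero
row or column margin carry no information and contribute nothing; a site
whose strata are all degenerate is reported with $p = 1$ and flagged.

Effect size is the Mantel–Haenszel common odds ratio
$\sum_k a_k d_k / n_k \,/\, \sum_k b_k c_k / n_k$, with a per-stratum
Haldane $+\tfrac12$ on all four cells of any stratum containing a zero
(the test statistic itself uses uncorrected hypergeometric moments — the
correction is an estimator device, not part of the null). Testing is
two-sided with direction assigned afterwards by the odds ratio against 1,
since sites are reported "for" each condition. Calls require
$\mathrm{OR} \ge 1.5$ in either direction and adjusted $p < 0.01$. Sites
enter the analysis only if **every** replicate of **both** conditions
meets the coverage floor (joint filtering; the retained universe size is
part of the output).

Calibration note: with the continuity correction the CMH test is
deliberately conservative (null rejection ≈ 0.5% at $\alpha = 1\%$ in
our null simulations). The package's calibration check therefore asserts
nominal rejection for the *uncorrected* statistic and conservativeness
for the corrected default.

## The simulator: what it emulates

`simulationConfig()` / `simulateRun()` generate a single-chromosome toy
transcriptome (gamma-distributed lengths, default mean 1.5 kb in the
200–4000 b range, yeast-like and single-exon), plant modification sites
uniformly at `mods_per_kb` (default 10/kb, which at these lengths gives a
median near the 15–20 sites/transcript regime reported for yeast), and
emit coordinate-sorted SAM, FASTQ, BED and ground-truth tables:

* **Errors.** Each covered base errs with probability `p_err_bg`
  (default 0.12 → ~88% identity) or `p_err_mod` (default 0.30) at planted
  sites, split 60/20/20 into substitutions / 1-base insertions / 1-base
  deletions. The split is configurable; real error decompositions are
  platform- and basecaller-dependent and no canonical split exists.
* **3′ bias.** In `rna` mode every read is anchored at its transcript's
  3′ terminus and its length back toward the 5′ end is geometric with
  per-base loss `truncation_p` (censored at the transcript length). This
  single-parameter monotone model reproduces the observed coverage decay
  of native-RNA libraries — 3′ adaptor ligation means 5′-truncated
  fragments are sequenced, full-length molecules from the 3′ end. It is a
  modelling choice, not an inferred distribution. The mechanistic
  consequence — planted sites near the 5′ end fall below the coverage
  floor and statistical cutoffs and are not called, while 3′-decile sites
  are — is a tested property of the pipeline.
* **Chimeras.** With probability `chimera_frac` a read is emitted as
  exactly two segments (primary + supplementary on another transcript,
  soft-clipped, linked by `SA` tags). Real chimeras can have more
  segments; two suffices for the classification logic being exercised.
* **Strand bias.** In `cdna` mode the reported orientation is drawn with
  `fwd_strand_frac` (default 0.9, emulating the strong first-strand bias
  of strand-switch libraries); in `rna` mode strand follows the
  transcript.
* **Qualities.** Per-read mean Q is a two-component truncated normal
  mixture — pass component N(9.5, 1.5) on [7, 41], fail component
  N(5, 1) on [1, 6.5) — so a fraction `q_pass_frac` (defaults 0.85 for
  rna, 0.50 for cdna, the observed pass rates of the two library types)
  sits at or above the cutoff. Per-base qualities are constant within a
  read because only per-read mean Q feeds the downstream filter.
* **Expression.** Per-transcript relative abundance is log-normal with
  `abundance_sdlog` (default 1, about a decade of spread); without it a
  count table would be a single Poisson mean and replicate correlations
  would be meaningless. At coverage 50 this yields log-scale replicate
  correlations of ~0.95–0.97, the regime reported for real replicate
  count tables.

Determinism: one seeded generator per run stage (transcriptome, truth,
reads use `seed`, `seed+1`, `seed+2`); identical configurations produce
byte-identical SAM/FASTQ/BED outputs, and the seed is recorded in the SAM
header.

**What the simulator does not model** — and hence what passing recovery
tests do not establish about real data: raw-signal artefacts and
basecaller-specific, sequence-context-dependent error (errors here are
i.i.d. given the site class); multi-position error footprints around a
modification (real modification signatures spread over ~5-mers); splicing
and poly-A lengths; coverage-dependent mapping artefacts; and any
particular production background-model construction, of which the three
modes here are explicit substitutes.

## Numerical choices and degenerate inputs

* One-sided Fisher p-values are hypergeometric survival probabilities;
  the suite verifies them against explicit enumeration to $10^{-10}$ for
  all tables with margins ≤ 30.
* Zero-coverage sites have no ESB and are skipped; zero-length test
  families return empty adjustments.
* `or_mh` with a zero denominator after correction is `NA` with a flag;
  direction is `NA` at `or_mh` exactly 1.
* The count-table correlation transform is $\log_{10}(n+1)$; zero-variance
  columns yield `NA` with a warning rather than an error.
* Per-transcript Jaccard excludes transcripts with an empty union
  (0/0 undefined); matching is exact by position and strand, with an
  optional window (default 0) for tolerant matching.
* Transcript annotations are sorted internally (with a warning) if
  supplied unsorted; a read overlapping two transcripts counts in both
  (≥1-base same-strand overlap, the `multicov` convention).

## Validation problem sizes

The shipped checks use: all 2×2 tables with margins ≤ 30 for the Fisher
oracle; 1,000 random 3-stratum tables for the CMH oracle; 5 × 2,000 null
sites at coverage 100 for calibration; 100 transcripts at coverage 200
with ~50 planted sites for profiling recovery (recall and precision ≥ 0.9
at OR ≥ 3, adjP < 1e-6); 1,000 sites / 100 planted at coverage 150, K = 3
for differential power (≥ 80% power, ≤ 2% null calls); and 5 seeds × 30
transcripts for the 3′-bias decile contrast. These sizes were chosen so
the whole validation runs in minutes on a laptop while leaving the
binomial error bars narrow enough for the stated margins.

## Known limitations

The pipeline calls *putative* modification sites: elevated error is a
proxy, not a chemical identification, and modification type (m6A vs.
others) is out of scope. The background-model modes are stand-ins for
whatever background a production caller derives from training data. The
CMH framework handles exactly two conditions; more require a different
stratified model. Exact stratified (network-algorithm) p-values and
Breslow–Day homogeneity testing are deliberately not implemented.
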