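---
title: "Methods: quantifying gene expression with a methylation reporter screen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying gene expression with a methylation reporter screen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(elmseq)
```

## The measurement model

The assay couples a randomized regulatory sequence (a promoter or a 5'-UTR)
to the *dam* gene, DNA adenine methyltransferase. Expressed Dam methylates
the adenine of GATC motifs; each construct carries four GATC sites upstream
of the promoter. Genomic DNA from the transformed library is split three
ways: undigested, digested with DpnI (cuts methylated G^mATC) and digested
with MboI (cuts unmethylated GATC). Only uncut fragments amplify, so after
sequencing, a variant's read frequency in the MboI pool reports methylated
(Dam-expressing) molecules and its frequency in the DpnI pool reports
unmethylated ones.

Per variant $i$ and condition, counts are depth-normalized with a
pseudocount,

$$\mathrm{CPM}_i = \frac{X_i + 1}{N + 1} \times 10^6,$$

and the expression statistic is the ratio of the two digestion survivors,

$$\mathrm{DAMRatio}_i = \frac{\mathrm{CPM}_i^{\mathrm{MboI}}}{\mathrm{CPM}_i^{\mathrm{DpnI}}}.$$

Higher ratios mean more methylation, hence more Dam. All downstream
analysis works on $\log_{10}$ DAMRatio. A variant enters the analysis only
if it was seen **more than 100 times** in at least one digestion pool
(strict inequality; the uncut pool is reserved for DNA-dosage
normalization of RNA abundances). Hemimethylated GATC sites resist both
enzymes; the simulator models this explicitly (below) and the package's
tests verify that hemimethylation compresses ratios toward 1 without
reordering variants.

## Read processing

Raw amplicon reads are reverse complements of the construct sense strand.
Filtering is by exact anchor match at template-fixed offsets: the dam
coding-sequence anchor, the screen-specific upstream anchor (the 4×GATC
cassette for the promoter screen, the fixed promoter for the UTR screens),
and, for the promoter screen, the fixed Pribnow box `TATAAT` inside the
randomized span. Quality scores are ignored; there is no error-tolerant
rescue — mismatched reads are rejected with a reason naming the first
failed anchor. A `floating = TRUE` mode searches for the anchors instead
of fixing their offsets and additionally rejects reads whose anchor
spacing is wrong (`length_mismatch`); it is off by default because the
construct layout is fixed.

Promoter-screen coordinates skip zero: −37…−13 are the 25 randomized
upstream bases (N25), −12…−7 the fixed `TATAAT`, −6…+1 the 7 randomized
downstream bases (N7), with +1 the theoretical transcription start (TSSs
in bacteria sit preferentially seven bases downstream of the Pribnow box).
UTR-screen variants occupy −25…−1 with +1 the A of the start codon;
position −26 is the fixed promoter +1 base (T for the strong promoter, A
for the weak one).

Reads with unexpected variant length in floating mode are rejected and
tallied rather than rescued — an explicit policy choice where the
procedure is otherwise under-determined.

## Replicate combination

Biological replicates are combined on the log10 scale: an ordinary
least-squares regression of replicate B on replicate A over their shared
variants (at least 50 required), B mapped through the inverse of the
fitted line onto A's scale, then the per-variant mean of available values.
Variants seen in one replicate keep their single mapped value. The choice
of "regress, map, then average" is recorded in the output metadata; the
alternative of averaging raw values would leave B's scale compression in
place.

## Mixture classification

Log ratios across a screen are bimodal: a low-productive peak and a
high-productive one. The package fits a univariate Gaussian mixture by EM
(k-means++ initialization, 20 restarts keeping the best log-likelihood,
tolerance $10^{-6}$ on the log-likelihood, at most 500 iterations, seed
recorded). `K = "auto"` chooses between 2 and 3 components by BIC — a
third component accommodates screens where the high peak is indistinct.
Components with standard deviation below $10^{-4}$ are pruned with a
warning. Screens are made comparable by subtracting the left-most
component mean ("standardization"), so the low-productive peak sits at
zero.

Class labels compare posteriors under the left-most ("low") and
right-most ("high") components only; a middle component's mass is
reported but never labels a variant, and exact ties go to "low". This
posterior rule, not a fixed ratio cutoff, also defines the
positive/negative sets for the predictors.

```{r mixture-example, eval = FALSE}
fit <- fit_mixture(dam$log10_damratio, K = "auto", seed = 1)
dam$std <- standardize(dam$log10_damratio, fit)
dam$label <- classify(dam$log10_damratio, fit)$label
```

## Positional statistics

Per (position, base) cell, the log2 odds ratio between classes with a
Haldane–Anscombe pseudocount of 0.5 per cell keeps zero counts defined;
the odds ratio cancels base-composition bias from library synthesis.
Fisher exact tests run per cell on the raw counts, Bonferroni-corrected
over all cells. Motif-group comparisons (extended −10 `TGN` variants,
alternative Pribnow boxes `TAAAAT`/`TACAAT`/`TAGAAT`/`TATAAT`, …) use
two-tailed equal-variance t-tests on log10 DAMRatio (Welch by flag),
Bonferroni-corrected across comparisons.

Shine–Dalgarno-like elements are called as the longest contiguous
Watson–Crick complementarity run between the −20…−1 window and the
anti-SD sequence (default `CCTCCT`, the reverse complement of the SD
consensus `AGGAGG`, in DNA alphabet), with a minimum run of 4. The
organism's true anti-SD tail is a configuration entry, not a claim; every
SD analysis should report the rule used. Because folding stability
confounds SD effects, SD comparisons are best stratified on folding
energy — bin window energies with `cut()` at 1 kcal/mol width and test
within bins, exactly as `exposure_compare()` does internally for
structure exposure.

## Epistasis by mutual information

Pairwise interactions are quantified as plug-in mutual information (in
bits) between base identities at two positions, computed on the
high-productive set, divided by a null: the mean MI over random subsets
of the **full library** drawn at the observed-set size. Library-synthesis
correlations and the plug-in estimator's small-sample bias appear
identically in numerator and denominator, so a ratio near 1 means no
class-specific interaction. Defaults: 10,000 draws in the API (1,000 in
the CLI — ratios are stable to about three decimals by 1,000 draws on
10⁴-sequence pools), drawn without replacement (with replacement by
flag), fixed seed, bit-identical reruns. MI is reported in bits; ratios
are unit-invariant.

## Folding energies

Folding runs behind a provider contract. The reference provider — used by
every test — is a deterministic Nussinov-style maximum base-pairing model
(Watson–Crick plus GU wobble, minimum hairpin loop 3) scored at
−1 kcal/mol per pair, with one maximizing dot-bracket structure. It is a
structural stand-in, not thermodynamics: correlation scans and recovery
properties are engine-agnostic, and a ViennaRNA-backed provider
(`fold_provider("vienna")`) gives real minimum free energies when
`RNAfold` is on the PATH. DNA is transcribed (T→U) before folding.

`window_scan()` correlates, across variants, each window's energy with
log10 DAMRatio over start positions −26…−1 and end positions −10…100
(no position 0; windows shorter than `min_len = 4` nt or extending past
the available sequence are NA). The realized window count is reported —
the admissible-window count depends on the length constraints, which are
configurable. The default exposure-analysis region is (−25, +30), the
region of maximum folding–expression correlation. Exposure comparisons
between classes stratify on window energy in 1 kcal/mol bins and combine
per-bin log2 exposed/hidden odds weighted by bin occupancy (bin width
`Inf` recovers the unstratified comparison).

Because the true dam coding sequence beyond its first 33 nt is not part
of the template definition, the template carries a fixed synthetic CDS
continuation so windows ending at +100 always have sequence; it is
labelled synthetic in the source.

## Predictors

Sequences are one-hot encoded (A=(1,0,0,0), C=(0,1,0,0), G=(0,0,1,0),
T=(0,0,0,1), concatenated per position). The naive Bayes classifier uses
a Bernoulli event model on these binary features with Laplace smoothing
1 — it quantifies what independent per-base contributions alone achieve.
The support-vector regressor predicts log10 DAMRatio with an
ε-insensitive tube (ε = 0.2) and a radial-basis-function kernel; C = 1
and bandwidth 1/#features are the library defaults, all exposed as
arguments. Folding features are appended for exactly those windows whose
folding–expression correlation was **positive on the training split** —
computing the scan on training data only avoids leakage, and the selected
window list is frozen into the feature-matrix metadata. Train/test splits
never share a variant. AUC is the rank-based Mann–Whitney form with
half-credit ties.

## TSS calling from gene-specific RNA-seq

5'-end RNA reads are filtered for the dam anchor `ATGAAGAAAAATCG`,
trimmed of their 6 barcode bases, and assigned to (variant, UTR length)
by exact suffix match of the UTR portion against each library UTR — reads
are 5'-truncated transcripts of known constructs, so suffix matching is
complete and alignment is unnecessary. Lengths under 15 nt are discarded
as unmappable; a 26-nt UTR must additionally start with the correct
promoter +1 base; reads matching more than one variant are discarded
rather than fractionally assigned.
$\mathrm{TPM}_{i,l} = N_{i,l} / N_{\mathrm{tot}} \times 10^6$ with
$N_\mathrm{tot}$ the anchor-filtered read total and no pseudocount. The
TSS of a variant is the modal UTR length, ties flagged and broken toward
the longer UTR so the theoretical +1 (a 26-nt UTR, labelled "N7") wins
over the +2 start ("N8", 25 nt). RNA abundance (summed TPM) is
normalized by log10 of the variant's uncut-pool DNA count; variants with
uncut counts ≤ 1 are flagged unnormalized.

## The simulator and what passing tests show

`simulate_library()` generates the ground truth everything is validated
against: uniform-random variants (composition bias optional), log-linear
true expression
$E = \exp(\sum_p w_{p,b} + \sum_{(i,j)} s\,[b_i = b_j] + \varepsilon)$,
methylation probability $m = E/(E + K_{1/2})$, and a high label iff $E$
exceeds a threshold. Chosen-once defaults: weights $N(0, 0.5)$ ln-units
per (position, base), centered per position; noise sd 0.3; $K_{1/2}$ and
the class threshold at the median of $E$, so methylation probabilities
straddle 0.5 and classes balance — the regime where the ratio statistic
is most informative and the assay's near-linear reporter range is
emulated. Per-variant TSS lengths are 25 nt for two thirds of variants
and 26 nt for the rest, mirroring the observed downstream start shift;
reads take the planted length with probability 0.7 and one or two bases
shorter with 0.2 and 0.1.

Digestion: each of the four GATC sites is independently hemimethylated
with probability $h$ (resists both enzymes), otherwise methylated with
probability $m$; a fragment amplifies only if all four sites survive, so
survival is $(h + (1-h)m)^4$ for MboI and $(h + (1-h)(1-m))^4$ for DpnI.
Site states are i.i.d. — processive methylation is not modelled — and
pools are multinomial draws at the requested depth over these survival
weights, i.e. the infinite-template limit of per-molecule sampling. The
hemimethylation model is a minimal reconstruction consistent with the
enzymology (hemimethylated GATC resists both digestions), declared as
such.

What the simulator does **not** emulate: PCR duplicates and amplification
bias, position-dependent sequencing error profiles (only a uniform
substitution rate is available), partial digestion, cross-contamination
between pools, and real promoter sequence grammar. Passing recovery
tests therefore demonstrate the pipeline's correctness — that the
statistics recover what the measurement model encodes — not that real
libraries meet the model's assumptions.

## Problem sizes and numerical choices

The test suite and the acceptance script use desk-scale versions of the
study conditions: 1,000 variants at 10⁶ reads/pool for ratio recovery;
20,000 draws for mixture recovery; 10⁴-sequence pools with 1,000 null
draws for epistasis calibration; 5,000 training / 2,000 test sequences
for the predictors; 500 variants at 2×10⁵ reads for TSS recovery. EM
tolerance is $10^{-6}$ with an sd floor of $10^{-4}$; odds and exposure
cells use a 0.5 pseudocount; ties are broken toward "low" (mixture
labels) and toward the longer UTR (TSS calls); all stochastic steps take
explicit seeds and are bit-reproducible.

## Known limitations

* The replicate-combination regression is one defensible reading of an
  under-specified procedure; the mapping used is recorded in output
  metadata.
* The stub folding model ranks windows by pairing capacity only; absolute
  energies and fine structure differ from thermodynamic engines.
* Plug-in MI is biased upward at small samples; the resampling null
  absorbs the bias in ratios, but the absolute MI columns should not be
  compared across set sizes.
* The SD rule and the anti-SD default are approximations; organisms with
  unusual 16S tails need the configuration entry changed.
* Per-pair MI ratios on small observed sets scatter substantially (the
  plug-in estimator's sampling noise scales like a scaled chi-square);
  the median across pairs is stable and planted interactions stand out,
  but individual off-pair ratios should not be over-read.
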