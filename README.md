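# elmseq

Analysis of **Dam-methylase reporter screens** read out by
methylation-sensitive restriction digestion and deep sequencing, for
people dissecting promoter and 5'-UTR sequence determinants of gene
expression in bacteria with massively parallel randomized libraries.

The assay couples a randomized promoter or 5'-UTR to *dam* (DNA adenine
methyltransferase). Expressed Dam methylates the GATC sites on its own
construct; splitting the library DNA into an undigested pool, a DpnI
digestion (cuts methylated G^mATC) and an MboI digestion (cuts
unmethylated GATC) turns expression into differential read survival.
Per variant *i*,

    CPM_i      = (X_i + 1) / (N + 1) * 1e6
    DAMRatio_i = CPM_i(MboI) / CPM_i(DpnI)

so a high DAMRatio means a highly expressed (methylated) variant.
Variants are kept when seen more than 100 times in at least one
digestion. Log10 ratios across a screen are bimodal; a Gaussian-mixture
fit standardizes screens (left peak to zero) and classifies variants as
high- or low-productive by posterior comparison.

On top of that core statistic the package provides the full downstream
toolkit: positional log2 odds ratios between classes, motif-group
t-tests, alternative Pribnow and start-codon scans, Shine–Dalgarno
detection, mutual-information epistasis against a library-resampling
null, folding-energy window scans behind a pluggable provider, naive
Bayes and ε-SVR expression predictors, TSS calling from gene-specific
5'-end RNA-seq, plate-reader growth slopes — and a generative simulator
with planted ground truth (sequence effects → expression → per-site
methylation incl. hemimethylation → digestion survival → reads) that
every stage is validated against.

## Worked example

Simulate a 5'-UTR library whose first randomized base acts as a strong
purine/pyrimidine switch, sequence it to 10^6 reads per pool, and run the
pipeline:

```r
library(elmseq)
w <- matrix(0, 4, 25, dimnames = list(c("A","C","G","T"), NULL))
w[c("A","G"), 1] <- 1.5; w[c("C","T"), 1] <- -1.5
sim    <- simulate_library(n = 1000, template = elm_template("utr_strong"),
                           weights = w, noise_sd = 0.3, seed = 1)
counts <- simulate_digestion_reads(sim, depth = 1e6, seed = 2)
dam    <- dam_table(counts)
fit    <- fit_mixture(dam$log10_damratio[dam$pass_filter], K = 2, seed = 3)
fit
#> Gaussian mixture over log10 DAMRatio (1000 values)
#>   K = 2 | BIC: K2 2340.9
#>      weight    mean     sd
#> low   0.476 -3.1190 0.2737
#> high  0.524  1.4825 0.5217
#>   standardization shift (left-most mean): -3.119
```

The fit finds the two expression regimes (low peak at log10 ratio −3.1,
high at +1.5); `standardize()` would shift the low peak to zero so
screens can be compared. Classification and recovery of the planted
truth:

```r
cl    <- classify(dam$log10_damratio, fit)
truth <- sim$truth[match(dam$variant, sim$truth$variant), ]
sum(cl$label == "high")                                    # 524 of 1000
cor(truth$m, dam$damratio, method = "spearman")            # 0.984
mean(cl$label == truth$label)                              # 0.976
```

The positional odds table pinpoints the planted determinant — the four
strongest cells are the purine/pyrimidine contrast at the first
randomized base (position −25):

```r
tab <- position_base_odds(dam$variant[cl$label == "high"],
                          dam$variant[cl$label == "low"],
                          positions = elm_template("utr_strong")$positions)
head(tab[order(-abs(tab$log2_odds)), ], 4)
#>   position base count_high count_low  log2_odds            p       p_bonf
#> 2      -25    C          0       244 -10.107403 1.012573e-98 1.012573e-96
#> 3      -25    G        276         0  10.050366 5.738424e-99 5.738424e-97
#> 4      -25    T          0       232  -9.962195 1.155944e-92 1.155944e-90
#> 1      -25    A        248         0   9.742299 2.059597e-86 2.059597e-84
```

So the screen's read-out, the mixture classes and the positional
statistics all recover the planted biology: purines at the first
transcribed base drive expression up (log2 odds ≈ +10), pyrimidines down.

## Documentation

The methods vignette (`vignettes/elmseq-methods.Rmd`) describes the
measurement model, every algorithmic choice and its rationale, the
simulator's assumptions, and what passing tests do and do not show about
real libraries.
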