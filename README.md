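# eRNAtools

Denoising and supervised prediction of enhancer RNA (eRNA) from CAGE-seq
expression, for regulatory-genomics analyses of enhancer activity.

Active enhancers transcribe short, unstable, bidirectional eRNAs. CAGE-seq
detects them as 5' capped transcript starts (TPM), but stochastic
transcription contaminates the low-expression range, so "TPM > 0" is a poor
definition of an expressed eRNA. `eRNAtools` addresses this in two stages:

**1. Statistical denoising.** TPM values above 0.001 are transformed as
`LogTPM = 10·ln(TPM) + 4`, rounded onto integer counts, and modeled as a
two-component mixture

    P(k) = a · Pois(k; u) + (1 − a) · NB(k; r, p)

where `a` is the probability a measurement is stochastic noise (Poisson,
mean `u`) and the signal component is negative binomial (size `r`,
probability `p`). Parameters are estimated by multi-start maximum
likelihood; the count threshold separating noise from true eRNA is the
interface of the two weighted components, and counts above it are called
`true_eRNA`.

**2. Supervised prediction.** Expression calls are combined with DNase
open-chromatin state to label regions PR (positive), FR (fuzzy) or NR
(negative). DNA methylation (whole region + 3 segments), H3K27ac/H3K9ac
coverage (same segmentation), the expression of the 10 nearest genes per
side with their maximum, and GC content form the feature matrix (7 standard
feature combinations). Random-forest (OOB-tuned) and XGBoost (5-fold
CV-tuned) classifiers are trained on PR/NR with a stratified 80/20 split
and evaluated by Sn, Sp, AUC (Mann–Whitney), MCC and F1; models transfer
across cells without refitting and can re-predict the fuzzy set.

A synthetic multi-omics generator (`simConfig()` / `simulateCell()` /
`simulateMultiCell()`) plants all of this structure with full ground-truth
bookkeeping, so every stage runs and is tested without external downloads.

## Worked example

```r
library(eRNAtools)

cfg  <- simConfig(n_regions = 3000L, seed = 1L)
cell <- simulateCell(cfg)

# denoise one CAGE sample
dn <- denoiseCage(cell$cage, sample = "cell1", seed = 1L)
dn$fit
#> MixtureFit (Poisson noise + negative-binomial signal)
#>   a = 0.8577  u = 2.0769  r = 4.5995  p = 0.2522
#>   loglik = -6518.710  threshold = 7  converged = TRUE
#>   noise side : kurtosis 0.435, skewness 0.797
#>   signal side: kurtosis 1.689, skewness 1.162
#>   Poisson GOF p-value (noise side): 5.12e-06

# label by expression call x open chromatin
lab <- assignLabels(cell$regions, dn$calls, cell$dnase)
table(lab$label)
#>   PR   FR   NR
#>  287  408 2305

# features (combination 2: methylation + H3K27ac + GC), train, evaluate
fm <- buildFeatureMatrix(cell$regions, methyl = cell$methyl,
                         h3k27ac = cell$h3k27ac,
                         sequences = cell$sequences, combination = 2L)
sp <- makeSplit(lab, seed = 1L)
x  <- featureValues(fm)
model <- trainModel(x[sp$train, ], binaryLabels(lab, sp$train),
                    combination = 2L, seed = 1L)
evaluateModel(model, x[sp$test, ], binaryLabels(lab, sp$test))
#> ErnaEvalReport
#>   Sn = 1.0000  Sp = 0.9935  AUC = 0.9982  MCC = 0.9715  F1 = 0.9744
#>   counts: tp=57 fp=3 tn=458 fn=0 (cutoff 0.5)
```

The fitted mixing weight (~0.86) is the planted noise fraction
(1 − class balance of 0.14); the threshold of 7 sits at the crossing of the
weighted Poisson(2) and NB(mean 12) components; and the held-out metrics
show the methylation + H3K27ac features recovering the planted positive
class almost perfectly. With `h3k27ac_enrichment = 1` and equal
`methyl_means` the same pipeline yields AUC ≈ 0.5, as it must.

A command-line wrapper with subcommands
(`simulate | denoise | label | overlap | features | train | predict |
evaluate`) is installed at `inst/scripts/erna_tools.R`; seeded runs are
byte-identical on repetition.

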