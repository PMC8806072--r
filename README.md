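# circrbp

Prediction of RNA-binding-protein (RBP) interaction sites on circular RNAs
from 101-nt sequence windows, for computational biologists studying
circRNA–RBP regulation and for method developers who need a fully
reproducible, CPU-scale reference implementation of this family of
sequence classifiers.

CLIP-seq experiments localise RBP binding as peaks; each peak centre,
extended 50 nt in both directions, yields a 101-nt positive window, with
negatives drawn from unbound fragments. `circrbp` classifies such windows
with an ensemble deep network:

* **Five sequence encodings** per window: k-nucleotide frequencies
  (k = 1, 2, 3; 84 dimensions), PV-DM paragraph vectors over overlapping
  10-mer "words", electron–ion interaction pseudopotential
  (A 0.1260, T 0.1335, C 0.1340, G 0.0806), nucleotide chemical
  properties (ring/function/hydrogen-bond triples), and accumulated
  nucleotide frequency (prefix densities).
* **Base network**: per-channel convolutions (128 filters), channel
  concatenation, a shallow kernel-3 convolution, six cascaded multiscale
  residual blocks (two parallel branches of three 64-filter convolutions
  at kernels 3 and 5, residual shortcut), hierarchical feature fusion
  into a 192-filter 1×1 convolution, dropout 0.4, a bidirectional GRU,
  and sigmoid self-attention `W = σ(H Hᵀ/√d)`, `out = W H`, followed by a
  dense sigmoid head. Trained with Adam (lr 0.001, batch 50, early
  stopping). Forward and backward passes are implemented in R on BLAS
  matrix operations and verified against numerical gradients.
* **AdaBoost ensemble**: weight-proportional systematic resampling per
  round, vote weights `α = ½ ln((1−ε)/ε)`, alpha-weighted mean of member
  scores.
* **Evaluation**: SE, SP, ACC, MCC (with the square-root denominator) and
  rank-based ROC AUC, with undefined denominators flagged rather than
  zeroed.
* **Synthetic benchmark generator**: fixed-length windows with a
  consensus/PWM motif planted in positives at configurable occupancy, so
  the whole pipeline is verifiable without external downloads.

## Worked example

```r
library(circrbp)

# 200 positives with a hard 8-nt consensus motif + 200 background windows
records <- generate_dataset(200, 200, seed = 1)

# redundancy filter -> stratified split -> embedding -> encoding ->
# AdaBoost training -> held-out evaluation, at the desk-scale configuration
result <- run_pipeline(records, config = desk_config(seed = 1))
result$metrics
#> # A tibble: 1 x 8
#>   dataset       n    se    sp   acc   mcc   auc undefined
#>   <chr>     <int> <dbl> <dbl> <dbl> <dbl> <dbl> <chr>
#> 1 synthetic    80     1     1     1     1     1 ""
```

The report reads: on the 80 held-out windows, sensitivity, specificity,
accuracy, Matthews correlation and ROC AUC are all 1 — the pipeline
recovers the planted motif perfectly. With `occupancy = 0` (no motif) the
same pipeline stays at chance (AUC ≈ 0.5), which is the null calibration
check. `tidy(result$ensemble)` lists per-round vote weights and weighted
errors; `plot_roc()` and `autoplot()` visualise ROC curves and training
histories.

The same pipeline is available from a shell:

```sh
Rscript inst/cli/circrbp simulate --out-dir data --n-pos 200 --n-neg 200 --seed 1
Rscript inst/cli/circrbp train --pos data/positives.fa --neg data/negatives.fa \
        --out-dir run1 --rounds 1 --seed 1
Rscript inst/cli/circrbp predict --checkpoint run1/ensemble.rds \
        --fasta data/positives.fa --out scores.tsv
```

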