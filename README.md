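# distecg

Distant transfer learning for ECG beat classification in R: QRS
beat segmentation, conditional-GAN auxiliary domains, adversarial
negative-transfer avoidance, and a compact 1-D CNN classifier — with a fully
synthetic data generator so everything runs and is testable on one CPU with
no downloads.

## The science

Annotated ECG corpora are scarce and heavily imbalanced, while large labeled
datasets exist in unrelated modalities. Transferring from such *distant*
sources directly usually fails (or actively hurts — *negative transfer*),
because the source and target distributions share almost nothing. This
package implements a three-stage bridge between distant domains:

1. **Beat segmentation.** A Pan–Tompkins-style front end (high-pass →
   low-pass → derivative → squaring → moving-window integration, followed by
   adaptive dual thresholds with search-back and a refractory period)
   locates R peaks and Q/R/S fiducials, and slices a recording into
   half-open inter-R beats. The detection low-pass
   `(1 − 2z⁻⁶ + z⁻¹²)/(1 − 2z⁻¹ + z⁻²)` is linear-phase with group delay 5
   samples and DC gain 31 dB (rounded from 20·log₁₀36) — both recomputed,
   not hard-coded, by `filter_characteristics()`.

2. **Auxiliary domains (conditional GANs).** For each source dataset a
   class-conditional GAN with a *logistic-mixture* latent space (mixture
   weights β softmax-parameterized, per-component locations γᵢ and
   non-negative scales δᵢ learned through the reparameterized draw
   `z = γᵢ + δᵢ⊙σ`, σ standard logistic) generates auxiliary domain 1;
   a GAN trained on the target generates auxiliary domain 2. Minority
   classes are oversampled simply by conditioning the generator. A
   regularizer `λ Σ βᵢ‖1 − θᵢ‖²` keeps component scales near one.

3. **Negative-transfer-avoidance transfer.** Each hop (source → aux 1 →
   aux 2 → target) trains a feature network F, classifier C and a joint/
   marginal discriminator D on the min–max objective
   `class_loss − σ · gan_loss`, where `gan_loss` is a four-term adversarial
   loss using a reserved *virtual label* y_v (so one discriminator plays
   both the marginal and the joint role), and `class_loss` adds a
   φ-weighted source cross-entropy term (`+ γ·mean(φ·CE_source)`) to the
   target cross-entropy. The instance weights φ can be grid-searched
   against held-out labeled-target loss (`phi_mode = "grid"`, the pipeline
   default), which automatically down-weights an unhelpful source — the
   classifier-level half of negative-transfer avoidance.

The final stage runs under stratified k-fold cross-validation on the target
and is compared against a target-only baseline trained with the identical
fold assignment and seeds, so improvements are paired, not incidental.

A 10-layer 1-D CNN (conv 50/128/stride 3 → batch norm → max pool → conv
8/32 → batch norm → max pool → conv 5/512 → conv 3/128 → dense 64 → softmax)
is provided as the beat classifier, with exact valid-padding shape
arithmetic. All networks run on a small hand-written engine (dense, conv1d,
batch norm, max pool; manual backprop verified against finite differences;
SGD-momentum and Adam), because no automatic-differentiation package is
assumed — training is deterministic given a seed.

## Quick start

Simulate a noisy recording with known R peaks, segment it, and inspect the
filter bank:

```r
library(distecg)

out <- synth_ecg(synth_ecg_spec(fs = 200, duration = 30, heart_rate = 72,
                                snr_db = 20, seed = 1))
fid <- detect_fiducials(out$signal)
fid
#> <fiducial_set> 36 beats
beats <- segment_beats(out$signal, fid)
length(beats)                                  # count(R) - 1
#> [1] 35
sum(out$truth$r_locs %in% fid$r_locs)          # all 36 R peaks hit exactly
#> [1] 36

ch <- filter_characteristics(build_segmentation_filters(200)$lowpass)
ch$group_delay; round(ch$dc_gain_db, 2)
#> [1] 5
#> [1] 31.13

length(enumerate_scenarios(letters[1:4], "ecg"))  # ordered source subsets
#> [1] 64
```

Run the full three-stage distant transfer on a synthetic shifted-domain
family (two sources, one label-scarce paired target), against the paired
target-only baseline:

```r
reg <- list(
  src_a  = synth_domain(synth_domain_spec(n = 150, dim = 4, n_classes = 3,
                                          delta = 0.8, cov_scale = 1.5, seed = 21)),
  src_b  = synth_domain(synth_domain_spec(n = 150, dim = 4, n_classes = 3,
                                          delta = 0.8, cov_scale = 1.5, seed = 22)),
  target = synth_domain(synth_domain_spec(n = 36, dim = 4, n_classes = 3,
                                          delta = 0.8, cov_scale = 1.5, seed = 21),
                        domain = "target"))
cfg <- pipeline_config(gan = gan_config(epochs = 1500, seed = 1),
                       schedule = transfer_schedule(rounds = 60),
                       cv_k = 3, aux_n = 90)
run  <- run_distant_transfer(transfer_scenario(c("src_a", "src_b"), "target"),
                             cfg, reg, seed = 2)
base <- run_baseline("target", cfg, reg, seed = 2)
run$report
#> <metric_report> n=36  spec=100.0  sens=100.0  acc=100.0 (%)
base
#> <metric_report> n=36  spec=98.6  sens=97.2  acc=97.2 (%)
percentage_improvement(run$report$overall["accuracy"], base$overall["accuracy"])
#> [1] 2.86
```

(Takes about a minute on one CPU; identical seeds give bit-identical
results.)

Ablation variants are plain switches on `pipeline_config()`:
`use_ganad = FALSE` removes the GAN-built auxiliary domains (direct
transfer), `use_domain_term = FALSE` drops the marginal (virtual-label)
discriminator terms, `use_feature_term = FALSE` drops the adversarial term
from the feature update (σ = 0), and `use_classifier_term = FALSE` drops the
weighted source classification term (γ = 0).

Train the CNN beat classifier directly:

```r
cnn <- build_cnn(input_length = 240, n_classes = 2)
d   <- synth_imbalanced_beats(c(40, 12), beat_len = 240, seed = 1)
fit <- train_classifier(cnn, d$x, d$y, classifier_config(epochs = 5, seed = 1))
mean(predict(fit, d$x)$labels == d$y)
```

A thin command-line front end is installed at
`system.file("cli", "distecg", package = "distecg")` with `segment`,
`simulate` and `enumerate` subcommands.

## Tests and reproducing the results

```sh
Rscript -e 'testthat::test_dir("tests/testthat", package = "distecg",
                               load_package = "installed")'
```

The suite (about 6 minutes on one CPU) contains unit/property tests per
module plus `tests/testthat/test-acceptance.R`, one block per acceptance
criterion: scenario combinatorics (64 / 256), the low-pass group delay and
DC gain, percentage-improvement arithmetic at 3 significant figures,
closed-form adversarial losses with brute-force scalar oracles (≤ 1e−6),
the logistic latent's excess kurtosis (1.2 ± 0.05 at n = 2×10⁵), noisy
R-peak recovery (≥ 0.99 sensitivity, ≤ 40 ms error, 60 beats at 20 dB SNR,
5 seeds), the positive-transfer property (full pipeline median ≥ baseline
over 5 seeds, with no ablation beating the full configuration beyond 1 SE),
and bit-identical same-seed reruns.

The analytic acceptance targets are recomputed from the installed package
by:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
# t3 (DC gain, dB, rounded): 31
# t4 (group delay, samples): 5
```

## Package layout

| File | Contents |
| --- | --- |
| `R/filters.R`, `R/fiducials.R` | detection filter bank, thresholds, QRS detector, beat segmentation |
| `R/ganad.R` | logistic-mixture latent, conditional GAN training, auxiliary-domain generation |
| `R/dfcnta.R` | virtual labeling, four-term adversarial loss, weighted class loss, stage training, φ grid search |
| `R/classifier.R`, `R/nn.R` | 10-layer 1-D CNN and the minimal NN engine |
| `R/pipeline.R` | scenario enumeration, three-stage pipeline, ablations, baseline |
| `R/evaluation.R` | specificity/sensitivity/accuracy, macro reports, improvement, stratified k-fold, imbalance ratios |
| `R/synthetic.R` | ECG simulator with exact R-peak truth, shifted vector domains, imbalanced beat sets |
| `R/io.R` | CSV round-trips and a minimal WFDB (.hea/.dat, formats 16 & 212) reader |

The methods vignette (`vignettes/distant-transfer-ecg.Rmd`) documents the
model, the optimization loops, the numerical choices, and known limitations
of the generators.
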