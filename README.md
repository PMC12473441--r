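# sitsense

Smart-sensing chairs instrument an ordinary office chair with two pressure
mats — one on the seat, one on the backrest, each a 32 x 32 grid of sensels
reporting integers 0–255 — and use the resulting dual contact maps to
monitor how a person sits. **sitsense** implements the full computational
pipeline of such a system in R, for researchers in posture monitoring and
ergonomics who want a reproducible, end-to-end testbed:

* a **synthetic dual-mat frame generator** for 19 sitting postures
  (`SP1` upright … `SP19` trunk rotated right, plus an auxiliary empty
  class `SP0`), emulating a single-sitter acquisition session of 151
  frames per posture;
* **preprocessing**: labeling, fixed-range min–max normalization
  (x/255), empty-frame removal;
* an **augmentation engine** with the five standard pressure-map
  transforms — Gaussian noise (level 0.5), shift (±10 cells), rotation
  (±30°), random erasing (10% of each mat), elastic deformation
  (α = 24, σ = 4);
* **five classifiers** behind one interface — decision tree, random
  forest, RBF-kernel SVM and k-NN with exhaustive grid search under
  5-fold cross-validated accuracy, and a shallow CNN
  (conv 32 → pool → conv 64 → pool → dense 128 → softmax over 19 classes,
  Adam + early stopping) implemented in compiled single-precision code;
* **evaluation**: confusion matrices, macro precision/recall/F1, and a
  sensor-resolution degradation study (bilinear downsampling to
  2×2 … 32×32 followed by retraining);
* a **sitting-quality engine**: Borg CR-10 risk scores per posture and
  the duration-decayed quality statistic

  QS = 1 / (1 + S + D·T),

  where S is the posture's risk score (1–10), T the minutes the posture
  has been held, and D a context-dependent decay factor (upright: 0 up to
  30 min, then 0.005; otherwise 0 up to 30 s, then 0.02), plus episode
  segmentation, session analytics and a canonical JSON history format.

## Worked example: scoring a one-hour session

```r
library(sitsense)

# a 1 Hz posture prediction stream: 35 min upright, 15 min leaning left,
# 10 min upright again
stream_t <- seq(0, 3600, by = 1)
stream_p <- c(rep("SP1", 2101), rep("SP3", 900), rep("SP1", 600))
tl <- segment_episodes(stream_t, stream_p)
tl
#>   posture  start    end duration_min
#> 1     SP1    0.0 2100.5    35.008333
#> 2     SP3 2100.5 3000.5    15.000000
#> 3     SP1 3000.5 3600.0     9.991667

s <- session_summary(tl)
s$per_posture
#>   posture minutes percent
#> 1     SP1      45      75
#> 2     SP3      15      25
s$mean_qs
#> 0.402
session_recommendations(tl)
#> Dominant posture: SP1 (45.0 min, 75% of the session).
#> Longest static episode: SP1 for 35.0 min.
#> SP1 held 35.0 min exceeded its static-upright threshold of 30.0 min; ...
#> SP3 held 15.0 min exceeded its non-upright threshold of 0.5 min; ...
```

The mean QS of 0.402 reflects that the neutral posture scores 0.5 while
fresh (1/(1+1)), the lean scores 1/8 (S = 7), and both episodes overran
their static thresholds so the decay factors bit into the score.

## Worked example: the classification pipeline

```r
ds    <- generate_dataset(sim_config(n_per_class = 151, seed = 42))  # 2869 frames
clean <- normalize_minmax(drop_empty(ds))
aug   <- augment_dataset(clean, augment_policy(copies_per_frame = 3, seed = 43))
parts <- split_dataset(aug, split_spec(seed = 44))                   # 80/10/10
cnn   <- train_model("cnn", parts$train, parts$val, seed = 45)
evaluate_model(cnn, parts$test)
#> <eval_report> n=1140 accuracy=0.9553 ...
```

On this synthetic dataset the five models reproduce the qualitative
ordering expected of the comparison — the CNN leads (0.955), followed by
the SVM (0.924), k-NN (0.858) and random forest (0.846), with the single
decision tree far behind (0.623). `run_pipeline()` executes the whole
six-stage flow (simulate → preprocess → augment → train → evaluate →
export) under one seed and writes artifacts plus a digest manifest to a
run directory.

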