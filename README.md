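# ss3fold

Alignment-free protein fold classification from three-state secondary
structure.

## The problem

In large, deeply diverged enzyme superfamilies — the glycosyltransferases
(GTs) being the motivating case — the structural fold is conserved while
primary sequences have diverged beyond alignability, so profile- and
alignment-based classification cannot cover the superfamily. Secondary
structure is a coarse observable that survives this divergence: the order
and lengths of helices, strands and loops carry the fold signal even when
no residue-level similarity remains.

`ss3fold` is for computational biologists who have per-residue three-state
secondary-structure annotations (H = helix, E = strand, C = coil, from any
predictor) and labels for part of their data, and who want to

1. classify folds and families without any alignment,
2. see *which residues* drive each classification,
3. map the landscape of a superfamily by clustering learned embeddings, and
4. flag families that likely adopt a **novel** fold, rather than
   force-assigning every query to a known class.

## The model

Sequences are one-hot encoded to a fixed width (channel order H, E, C;
end padding `[0,0,0]` with a pad mask). A multitask CNN with attention
classifies folds and families jointly:

* **Block 1**: three stride-1 convolution layers (kernels 3/7/15), each
  with batch norm, ReLU, and a channel + spatial attention refinement — no
  pooling, so every activation maps to a residue and per-residue Grad-CAM
  profiles can be extracted from any layer;
* **Block 2**: a masked average-pooling bridge, three convolution blocks
  with local max pooling, then per-channel global max pooling giving a
  fixed-length embedding for UMAP + Gaussian-mixture clustering;
* two softmax heads (fold, family) trained with summed cross-entropy.

For open-set recognition, Block 1 is frozen as an encoder and a mirrored
deconvolution decoder is trained per known fold cluster. The masked
reconstruction error of a sequence (squared error over the 3 channels,
averaged over real residues only)

    RE = (1/n) * sum_t || Y_t - Yhat_t ||^2

is small for folds seen in training. A type-I extreme-value (Gumbel) fit to
the training errors calibrates 95%/99% upper limits and their midpoint; a
family's median RE against these thresholds, together with a per-cluster
fold assignment score

    FAS_ab = ((OOC_b - RE_a) * (OOF_b - OOC_b) / (OOF_b - RE_b) - thres) * 100

classifies it as a **known** fold (assigned to the best-scoring cluster), a
**variant** of known folds, or a **novel** fold, with a confidence tier.
A synthetic fold-grammar simulator (`sim_config()`, `sample_dataset()`)
generates archetype/family/sequence hierarchies with controlled noise and
held-out novel archetypes, so the entire workflow is testable end to end
without external data. See the methods vignette
(`vignettes/ss3fold-methods.Rmd`) for every model and calibration detail.

## Worked example

```r
library(ss3fold)
library(withr)

# two training fold archetypes, one held-out novel archetype
sim <- sim_config(n_archetypes = 2, families_per_archetype = 2,
                  seqs_per_family = 50, insertion_rate = 1,
                  noise_rate = 0.03, novel_archetypes = 1,
                  max_len = 192, seed = 101)
d <- sample_dataset(sim)

cfg <- model_config(L_max = 192, block1_filters = c(8, 16, 16),
                    block2_filters = c(16, 16, 16), attention_reduction = 4,
                    batch_size = 16, max_epochs = 15, patience = 15,
                    lr = 3e-3, seed = 31)
model <- build_model(cfg, folds = unique(d$train$fold),
                     families = unique(d$train$family))
val <- with_seed(9, sample(nrow(d$train), 40))
model <- train_classifier(model, d$train[-val, ], d$train[val, ])
model
#> ss3 fold/family classifier (trained)
#>   L_max 192 | block1 8/16/16 filters, kernels 3/7/15 | block2 16/16/16 filters
#>   2 folds, 4 families, 7,861 parameters

predict(model, d$train[val, ][1:3, ])$calls
#> # A tibble: 3 × 5
#>   id                    fold_call     fold_prob family_call      family_prob
#>   <chr>                 <chr>             <dbl> <chr>                  <dbl>
#> 1 dual-rossmann_f2_s037 dual-rossmann     0.986 dual-rossmann_f2       0.920
#> 2 rossmann_f2_s003      rossmann          0.834 rossmann_f2            0.725
#> 3 rossmann_f1_s006      rossmann          0.911 rossmann_f1            0.677
```

Each sequence gets posterior probabilities for both tasks; here the
held-out sequences are all classified into their true archetype. Fitting
the open-set detector on the training partition and scoring the held-out
*novel* archetype:

```r
os <- fit_openset(model, d$train[-val, ], decoder_filters = c(24, 16, 12),
                  epochs = 10, lr = 3e-3, seed = 41)
os$calib
#> EVD calibration (n = 160): loc 0.1476, scale 0.0290
#>   CI upper limits: 0.2338 (95%), 0.2811 (99%); midpoint threshold 0.2574

score_unknown_families(os, d$novel)
#>       family n_seqs       mRE best_cluster  best_FAS verdict confidence
#> 1 novel01_f1     50 0.3581609     rossmann -33.54572   novel       high
#> 2 novel01_f2     50 0.3410031     rossmann -33.53094   novel       high
```

Both families of the archetype the model never saw reconstruct poorly
(median RE ≈ 0.35, far above the calibrated 0.257 midpoint threshold) and
every per-cluster fold assignment score is negative, so they are called
novel folds with high confidence — exactly the behaviour the detector
exists for. Per-residue interpretation is one call away:

```r
prof <- grad_cam(model, d$train[1:5, ], layer = 2,
                 target_class = "rossmann", task = "fold")
write_cam(prof, "cam.tsv")   # id, layer, position, state, cam in [0,1]
```

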