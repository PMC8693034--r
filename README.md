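# protgeom

Inter-residue protein geometry prediction in R: coevolution features
from multiple sequence alignments, multi-scale (Res2Net-style)
residual networks for de novo and template-based prediction, an
axial-attention module that fuses multiple homologous templates,
confidence-weighted combination of the two predictions, contact-map
evaluation, and a distance-geometry realiser that turns predicted
distance distributions into coarse-grained coordinates.

## Who this is for

Structural bioinformaticians and methods developers who want a fully
inspectable, desk-scale implementation of a trRosetta-family geometry
prediction pipeline — every stage from A3M file to Cβ-trace PDB runs
on one CPU, on synthetic data the package generates itself, with
every numerical component unit-tested against independent oracles.
It is a laboratory for the *method*, not a production predictor: no
pretrained weights ship with it, and no claim is made about accuracy
on real proteins.

## The model

For each residue pair (i, j) the networks predict categorical
distributions over binned geometry:

* **d** — Cβ–Cβ distance: 36 bins of 0.5 Å over [2, 20) Å,
* **ω** — Cα–Cβ–Cβ–Cα dihedral: 24 bins of 15° (symmetric, like d),
* **θ** — N–Cα–Cβ–Cβ dihedral: 24 bins of 15° (asymmetric),
* **φ** — Cα–Cβ–Cβ planar angle: 12 bins of 15° (asymmetric),

each with a shared *no-contact* bin (d ≥ 20 Å), for 37/25/25/13 bins.

The **FM network** consumes a 526-channel tensor per pair — tiled
one-hot/profile/entropy features (2 × 42 channels) plus
inverse-covariance couplings with their APC-corrected norm (441 + 1
channels) — through groups of Res2Net blocks, whose bottleneck splits
into s = 4 channel subsets processed hierarchically
(y₁ = x₁, y₂ = K₂(x₂), yᵢ = Kᵢ(xᵢ + yᵢ₋₁)) with dilated 3×3
convolutions, instance normalisation and ELU.

The **TBM network** reuses the FM stem and first two groups frozen,
concatenates their output with a 100-channel one-hot encoding of up
to 10 *good* templates (probability > 60% or E-value < 0.001)
combined by axial attention over the template axis, and runs four new
groups — six groups in total.  The final posterior is the per-pair
convex combination

    w_TBM(i,j) = Σ_k w_k(i,j) · s_k(i,j),   s_k(i,j) = (s_k(i)+s_k(j))/2,
    p(i,j) = (1 − w_TBM) · p_FM + w_TBM · p_TBM,

with w_TBM ≡ 0 when no good template exists.  Contacts are scored as
the summed probability of the bins with d ≤ 8 Å and assessed by top-k
precision within separation classes (short [6,12), medium [12,24),
long [24,∞)).

The networks and their training (Adam on a four-head cross-entropy,
with per-epoch MSA subsampling and crop/stitch length augmentation
under a 260-residue cap) run on a small tape-based reverse-mode
autodiff over base-R arrays built into the package — every operation
is gradient-checked in the test suite.

## Worked example

Train the tiny profile on 20 synthetic targets and evaluate a
held-out one (about a minute on one CPU):

```r
library(protgeom)
set.seed(7)

targets <- gen_dataset(24, L = 48)          # compact toy proteins + MSAs
fit <- train_fm(targets[1:20], epochs = 6, augment = FALSE, seed = 7)

tgt  <- targets[[21]]                        # held out
pred <- predict_geometry(tgt$msa, fit$net)   # FM-only (no templates)
pred
#> <geometry_prediction> L = 48, 0 template(s), mean w_TBM = 0.000

cp <- contact_probability(pred$posterior$dist)
contact_precision_report(cp, tgt$maps$d)
#>         class k_label  k precision
#> 4        long       L 48 0.3333333
#> 6        long     L/5 10 0.4000000
#> 7 medium+long       L 48 0.3333333
#> ...
```

Top-L/5 long-range precision of 0.40 against a ~0.15 contact density
baseline after one minute of CPU training: the network has picked up
the planted coevolution signal.  (The acceptance run below trains on
150 targets and reaches far higher precision.)

Realise coordinates from a sharp posterior — here built from a
noise-free template via the encode/decode path — with the 120-decoy /
keep-5 protocol:

```r
set.seed(7)
tgt   <- gen_target(L = 48, n_templates = 1, template_noise_sd = 0)
stack <- build_template_stack(tgt$hits, tgt$templates, 48)
post  <- symmetrize(posterior_from_labels(decode_template(stack$feats[[1]])))

set.seed(8)
res <- decoy_protocol(expected_distance(post$dist))
kabsch_rmsd(res$model$xyz, tgt$maps$cb)
#> [1] 0.2747  # Angstrom, after optimal superposition
```

A command-line front end over the same functions lives at
`inst/cli/protgeom.R` (`simulate`, `features`, `predict`, `realize`,
`eval` subcommands).

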