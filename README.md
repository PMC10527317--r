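# copdfuse

Multi-modal classification of COPD severity stage (early GOLD 1–2 vs
advanced GOLD 3–4) from paired clinical data: a table of physiological and
biochemical (PB) indicators and a 3D lung CT volume per patient. The
package implements the full method as reusable, tested R code, with a
synthetic paired-modality generator so every stage can be exercised and
benchmarked without access to hospital data.

## The method

* **PB branch** — indicators become nodes of a graph with edges wherever
  the absolute training-set Pearson correlation exceeds 0.3. Node states
  update by neighbor-**mean aggregation**, a dense map with ReLU and
  dropout, and L2 normalization per layer
  (`h_i ← σ(W[h_i ∥ mean_{j∈N(i)} h_j])`, `h_i ← h_i/‖h_i‖₂`); a **TopK
  pooling** layer keeps the `⌈kN⌉` nodes with the largest projection
  score `z = Xp/‖p‖`; a multi-scale readout concatenates mean- and
  max-pooled states per layer and sums them (`s = Σ_l [mean ∥ max]`),
  giving the 64-d modality vector `z_a`.
* **CT branch** — Hounsfield units normalized by
  `I = (H − HU_min)/(HU_max − HU_min)`, ±15° axial rotation augmentation,
  center-crop and trilinear resize; a 3D residual CNN (full
  `resnet50_3d`, or the `resnet_lite_3d` desk-scale profile) produces the
  64-d vector `z_v`.
* **Fusion** — low-rank multi-modal fusion (LMF) computes the full
  tensor-fusion contraction through rank-r per-modality factors,
  `h = Σ_i (w_a^{(i)} z_a) ∘ (w_v^{(i)} z_v)`, without materializing
  `W·(z_a ⊗ z_v)`; each modality stream then passes a **cross-modal
  transformer block** (queries from the modality, keys/values from `h`;
  `softmax(Q_m K_nᵀ/√d_k) V_n`) and a self-attention block; pooled
  streams are concatenated and classified by an MLP, trained end to end
  with cross-entropy.
* **Indicator identification** — pooling scores shortlist candidate
  indicators; each is then removed (training-mean substitution) and the
  accuracy drop ranks them; group differences are tested with
  independent two-sample t-tests on z-scored values.

There is no neural-network framework dependency: the networks, a small
reverse-mode autodiff tape and Adam are implemented in the package, with
Rcpp kernels for the 3D convolutions.

## A worked example

```r
library(copdfuse)

# paired synthetic data with complementary PB/CT signals
spec <- synthetic_spec(n_samples = 300, modality_signal = "complementary",
                       seed = 11)
ds <- generate_paired_dataset(spec)

# what an ideal classifier could achieve under this generative model
unlist(bayes_accuracy(spec))
#>        pb        ct     joint
#> 0.8145714 0.7852422 0.8797000

# clean the table (3-sigma screen + class-restricted KNN imputation)
prep <- preprocess_pb(ds$table)
prep$report$flag_rate
#> [1] 0.01680556

# train and evaluate the fused model against each single branch
fg <- fusion_gain_experiment(spec = spec, seeds = 1:5)
fg$per_seed
unlist(fg$summary)

# rank indicators on PB-only data with four planted signals
ir <- indicator_recovery_experiment(seeds = 1:5)
ir$per_seed
```

`fusion_gain_experiment()` prints per-seed test accuracies of the PB-only,
CT-only and fused models — the fused mean exceeds both unimodal means —
and `indicator_recovery_experiment()` reports how many of the four planted
indicators (BMI, APTT, weight, albumin in the generator's naming) the
pooling + ablation shortlist recovers per seed, along with the ablation
drop of pure-noise indicators.

A thin command-line surface wraps the same functions:

```sh
inst/cli/copdfuse simulate   --config cfg.yaml --data data/
inst/cli/copdfuse preprocess --config cfg.yaml --data data/ --out run/
inst/cli/copdfuse train-fusion --config cfg.yaml --data data/ --out run/
inst/cli/copdfuse select-indicators --config cfg.yaml --data data/ --out run/
```

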