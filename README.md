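# morphoprompt

Morphology-enriched prompt building (MEP) and its evaluation protocol for
annotation-scarce histopathology image datasets.

## The problem

Text-to-image latent diffusion models need descriptive captions to be
fine-tuned, but histopathology patch datasets (e.g. PCam-style 96 × 96 px
H&E patches) typically carry nothing more than a binary label per patch:
0 = healthy, 1 = cancer. A caption built from the label alone —
`"Histology image of cancer tissue"` — collapses an enormously diverse set
of tissue morphologies and staining profiles into two prompts, and the
generative model fine-tuned on them inherits that collapse.

MEP enriches the captions with *image-derived* structure, with no extra
annotation effort:

1. **Feature extraction** — every patch is embedded by a fixed feature
   extractor (a pluggable contract; deep self-supervised extractors adapt
   in, and a cheap deterministic 34-dimensional reference extractor is
   bundled so everything runs on a desk).
2. **Clustering** — the feature vectors are clustered with k-means, and the
   number of clusters k is chosen by minimizing the SD validity index over
   a scan (default 2 ≤ k ≤ 50):

   SD(k) = α · Scat(k) + Dis(k),

   where Scat(k) = (1/k) Σᵢ ‖σ(Cᵢ)‖ / ‖σ(X)‖ measures average
   within-cluster scattering (σ(·) is the per-dimension variance vector),
   Dis(k) = (D_max / D_min) Σᵢ (Σⱼ ‖vᵢ − vⱼ‖)⁻¹ measures inter-centroid
   separation over centroids v, and α = Dis(k_max) at the largest scanned
   k. Smaller is better.
3. **Prompt completion** — each patch gets the caption
   `"Histology image of LABEL tissue, morphology type INDEX"`, where INDEX
   is its cluster index (rendered as an English word, e.g. "five", or as a
   numeral).

Around that core, the package implements the full evaluation protocol:
near-uniform prompt balancing with a train/validation split, a JSON-Lines
caption manifest for fine-tuning stacks, Fréchet Inception Distance (FID)
and improved precision/recall on embedding sets, a projection-based
coverage analysis (projector fitted on real data only), and a mixed
real/synthetic classifier benchmark over data regimes × augmentation
ratios × folds with AUC reporting. Synthetic stain-like patch and
feature-mixture generators with known ground truth make every stage
testable without any download.

## Worked example

```r
library(morphoprompt)

# a synthetic stain-like dataset with 3 latent morphology types
ps <- make_patch_dataset(n = 300, n_morphologies = 3, cancer_fraction = 0.5,
                         image_size = 96, seed = 42)
fm <- extract_features(ps)                  # 300 x 34 reference features
scan <- select_k(fm, k_min = 2, k_max = 8, seed = 1)
scan
#> <kscan_result> scanned k in [2, 8]; chosen k = 3 (SD = 1.29, alpha = 16.46)

prompts <- build_prompts(fm$ids, ps$true_label, scan$model$assignments)
head(prompts$caption, 3)
#> [1] "Histology image of cancer tissue, morphology type zero"
#> [2] "Histology image of healthy tissue, morphology type two"
#> [3] "Histology image of cancer tissue, morphology type one"
length(unique(prompts$caption))             # 2 labels x 3 clusters
#> [1] 6

write_manifest(prompts, "captions.jsonl")   # hand-off to a fine-tuning stack
```

The SD-index scan recovers the three latent morphology recipes built into
the fixture, and the captions enumerate label × cluster combinations.

Generation metrics behave the way mode collapse predicts — a synthetic set
matching the real distribution scores low FID and balanced
precision/recall, while a collapsed single-mode set keeps precision but
loses recall and explodes FID:

```r
evaluate_generation(real_embeddings, matched_embeddings, k_nn = 3)
#> <metric_report> FID = 3.233, precision = 0.832, recall = 0.818 ...
evaluate_generation(real_embeddings, collapsed_embeddings, k_nn = 3)
#> <metric_report> FID = 1178, precision = 1.000, recall = 0.002 ...
```

## Command line

An `exec/mep` launcher exposes the pipeline as subcommands:

```sh
mep simulate --out data --n 1000 --morphologies 4 --seed 1
mep extract  --images data/images --labels data/train_labels.csv --out feats.csv
mep select-k --features feats.csv --out scan.json --assignments clusters.csv
mep prompt   --labels data/train_labels.csv --assignments clusters.csv --out prompts.csv
mep balance  --prompts prompts.csv --out balanced --total 51000 \
             --train-size 50000 --val-size 1000
mep manifest --prompts prompts.csv --out captions.jsonl
mep metrics  --real real_emb.csv --syn syn_emb.csv --out report.json
mep bench    --real real.csv --syn syn.csv --val val.csv --test test.csv --out bench
```

All subcommands accept `--config cfg.yaml` and thread `--seed` to every
stochastic stage.

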