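# ionseg

Segmentation and topological quantification of intracellular organelle
networks (endoplasmic reticulum, mitochondria) in fluorescence microscopy
images, for cell biologists and image analysts who need masks *and* the
network statistics behind them.

Organelle networks are dense planar webs of tubules meeting at junctions and
enclosing meshes. `ionseg` implements:

* a **multi-resolution encoder (MRE)** on a U-Net backbone: five random
  crops $I_j$ of sizes $(H/2^j, W/2^j)$, per-stage low-level extractors
  $LF_j$ (channels $64\cdot2^j$ at the canonical width), mixture feature
  maps $MF_j = [LF_j, DF_j]$ as skip connections, and **nine prediction
  heads** (five multi-resolution, four up-sampled to full size);
* the **hierarchical fusion loss**
  $L_{hf} = \sum_{j=1}^4 \alpha_j L^{up}_j + \sum_{j=0}^4 \beta_j L^{ml}_j$
  with $\beta_0 = 0.5$ and the eight auxiliary weights $0.0625$, each term
  a soft IoU loss
  $1 - \sum \hat y y \,/\, (\sum(\hat y + y - \hat y y) + \eta)$;
* the preprocessing ablation set (CLAHE, standardization, edge enhancement,
  inversion) with the selected pipelines `er_default` (CLAHE) and
  `mito_default` (CLAHE + standardization);
* topology-aware evaluation: IoU, accuracy, AUC, centerline Dice, Betti
  error ($|\Delta\beta_0|+|\Delta\beta_1|$, or $|\Delta\beta_1|$ for
  vessel-style data) and Hausdorff distance;
* a **skeleton-to-graph pipeline**: blob removal, topology-preserving
  thinning, junction/tubule graph extraction, and six network properties
  (degree, degree centrality, closeness centrality, effective size, mesh
  density, junction density) with a predicted-vs-truth t-test harness;
* a **synthetic tubular-network generator** with exactly known masks and
  topology (components, loops, junctions, edge lengths, mesh areas), so the
  whole pipeline is testable without microscope data.

The network runs on a self-contained reverse-mode autodiff core
(Rcpp/RcppArmadillo); no external deep-learning framework is required.

## Worked example

```r
library(ionseg)

# a synthetic ER-like image with known topology
d <- generate_dataset(1, list(height = 96, width = 96, n_seeds = 12,
                              loop_fraction = 0.3), rng_seed = 7)[[1]]
d
#> synthetic_sample syn0001: 96x96 px, beta0=1 beta1=3 junctions=7
unlist(d$truth)
#>             beta0             beta1    junction_count total_edge_length
#>            1.0000            3.0000            7.0000          247.0323
#>         mesh_area  convex_hull_area
#>          490.4921         2543.0091

# train a reduced MRE U-Net on this one sample and segment it
img <- apply_pipeline(d$image, "er_default")
model <- build_mre_unet(mre_config(base_channels = 8, depth = 4,
                                   input_size = c(96, 96)), rng_seed = 1)
log <- train_model(model, list(list(image = img, mask = d$mask)),
                   steps = 50, rng_seed = 1)$log
round(c(first = log$total[1], last = log$total[50]), 3)
#> first  last
#> 0.924 0.788
mask <- segment(model, img, rng_seed = 42)

# score it: volumetric + topological + distance metrics
prob <- predict(model, img, rng_seed = 42)$upsampled_preds[[4]]
round(evaluate_masks(prob, mask, d$mask), 2)
#>     iou   acc   auc cldice betti_error hausdorff
#> 1 79.18 98.35 99.39  97.27           2     41.73

# reduce the true mask to a junction/tubule graph and its network properties
round(network_summary(d$mask, min_area = 30, merge_dist = 8), 3)
#>   mean_degree mean_degree_centrality mean_closeness_centrality
#> 1       2.571                  0.367                    51.686
#>   mean_effective_size mesh_density junction_density n_junctions n_tubules
#> 1               0.857        0.146             0.03           7         9
#>   total_length
#> 1      234.38
```

`mean_degree` is tubules per junction; `mesh_density` the fraction of the
network's convex hull enclosed by meshes; `junction_density` junctions per
pixel of tubule length. After only 50 steps the overfit model reproduces
most of the mask (IoU 79, clDice 97) with a small topology gap (Betti error
2); the large Hausdorff distance comes from one residual false blob far
from the network — exactly the kind of error the topological and distance
scores are there to expose.

A YAML-driven command line covers the same flow
(`generate | train | evaluate | analyze`):

```sh
Rscript inst/cli/ionseg.R generate --config run.yaml
Rscript inst/cli/ionseg.R train    --config run.yaml
```

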