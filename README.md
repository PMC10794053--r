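# ShootCount

Counting new shoots — current-season growth tips — in tree-crown imagery by
density-map regression. The package is aimed at forestry/phenotyping work
where crowns are detected as boxes and the shoots inside each crown are
annotated as dots: it converts dot annotations into ground-truth density
maps with a geometry-adaptive Gaussian kernel, trains a small convolutional
density regressor under a composite loss built around **unbalanced entropic
optimal transport with a perspective-guided exponential transport cost**,
and evaluates both detection (precision / recall / AP at an IoU threshold)
and counting (MAE / MSE). A synthetic crown/shoot scene generator with a
height-dependent point density makes the whole pipeline testable end to end
without field data.

## The model

A ground-truth density map places a unit-mass Gaussian at every annotated
shoot, with bandwidth `sigma_j = beta * (mean distance of point j to its k
nearest neighbours)` (defaults `k = 3`, `beta = 0.3`), truncated at the
image boundary and renormalized so that `sum(grid) = count` exactly.

Training minimises, per image,

    L = smoothL1(sum(a) - m) + lambda1 * L_UOT + lambda2 * MSE(D, D')

where the core term couples the flattened predicted density `a` to unit
masses `b = 1_m` on the annotated dots:

    L_UOT = min_{P >= 0} <C, P> - eps * sum P log P
            + tau * ||P 1_m - a||_2^2 + tau * ||P' 1_n - b||_1

with `eps = 0.05`, `tau = 0.5` by default. The transport cost is
`C_ij = exp(L_ij / eta_ij)` with `L_ij` the Euclidean distance in
height-normalized coordinates and `eta_ij` the mean of the two locations'
normalized image heights — so the same pixel distance is costlier where
objects appear denser. The solver (mirror descent with exact
coordinate/exchange/cycle polish) is validated against brute-force and
linear-programming oracles; the loss gradient uses the envelope rule and is
validated against finite differences.

## Worked example

```r
library(ShootCount)

## a labelled synthetic scene: one crown, exactly five shoots
sc <- generateScene(sceneConfig(shootsPerCrown = c(5, 5)), 1)
sc$points
#> PointAnnotation 'scene_0001' (64 x 64 px): 5 points

## ground truth density: the grid sums to the count
d <- renderDensity(sc$points)
densityCount(d)
#> [1] 5

## the unbalanced OT core on the smallest possible instance
solveUot(a = 1, b = 1, C = matrix(1, 1, 1), eps = 0.05, tau = 0.5)
#> TransportPlan 1 x 1: objective 0.892198, 8 iterations, converged

## the 7:1.5:1.5 dataset split
lengths(splitDataset(seq_len(313), ratios = c(7, 1.5, 1.5), seed = 1))
#> train   val  test
#>   219    47    47
```

The five-point density map sums to the annotated count because every
kernel is renormalized after boundary truncation; the 1x1 transport
objective is the scalar minimum of `p - 0.05 p log p + 0.5 (p-1)^2 +
0.5 |p-1|`, which a grid search reproduces to five decimals; and the split
sizes follow the deterministic remainder-based rounding rule.

A full training run at desk scale (60 synthetic scenes, 30 epochs, one CPU,
about a minute):

```r
r <- countRecoveryExperiment(seed = 1)
c(trained = r$valMAE, baseline = r$baselineMAE)
#>   trained  baseline
#> 0.9824105 6.6875000
```

The trained counter's validation MAE beats the mean-count baseline by a
factor of about seven on this seed.

There is also a command-line driver for the whole workflow
(`generate`, `density`, `train`, `count`, `eval`, `crop`):

```sh
Rscript "$(Rscript -e 'cat(system.file("scripts","shootcount.R",package="ShootCount"))')" \
  generate --out scenes --n-images 8 --seed 1
```

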