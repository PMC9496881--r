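# swarmseg

Segmentation of hyperintense brain lesions from 2-D MRI-like image pairs,
for image-analysis researchers who want a fully inspectable, classical
(non-learned) baseline. The method needs two co-registered grayscale
images — a diseased scan and a disease-free reference of the same
anatomy — and proceeds in three stages:

1. **Skull-stripping.** Threshold (Otsu by default) → binary hole filling →
   disk erosion → largest connected component; both images are masked with
   the intersection of their brain masks.
2. **Region-of-interest search.** Particle swarm optimization over the
   positions of a rectangular block, maximizing a two-way fixed-effects
   ANOVA contrast between the candidate block *C* (diseased image) and the
   co-located reference block *R*. With factor *A* = image source
   (*a* = 2), factor *B* = block column (*b* = *w*) and the *h* rows of a
   column as replicates, the fitness is

   `fitness(C, R) = MSA/MSE + MSB/MSE`

   where `MSA = SSA/(a-1)`, `MSB = SSB/(b-1)`, `MSE = SSE/(N - ab)` and
   `SST = SSA + SSB + SSAB + SSE`. Large `MSA` means the block's mean
   intensity differs between the two scans; large `MSB` means strong
   column structure; both signal abnormal tissue. Fitness evaluations are
   memoized per integer block position. A sum-of-absolute-differences
   fitness (`sum(|C - R|)`) and an exhaustive-search oracle are provided
   for comparison and validation.
3. **Segmentation.** K-means (K = 2) on the raw intensities of the best
   block; the brighter cluster is labeled tumor, yielding a full-frame
   binary mask.

Masks are scored against ground truth with Dice `2TP/(2TP+FP+FN)`,
Jaccard `TP/(TP+FP+FN)` (related by `D = 2J/(1+J)`), Pearson correlation
and RMSE. A seeded phantom generator (elliptical brain, bright skull ring,
Gaussian tissue noise shared between the pair, hyperintense tumor disk)
makes every stage testable without any external data.

## Worked example

```r
library(swarmseg)

pair <- generate_phantom(phantom_spec(64, 64))   # seeded default phantom
fit  <- swarmseg(pair$diseased, pair$reference,
                 truth = pair$tumor_mask, seed = 7)
summary(fit)
#> Three-stage tumor segmentation (skull-strip / PSO block search / K-means)
#>   fitness: anova; seed 7
#>   ROI: block: rows 22..37, cols 31..46 (16x16)
#>   best fitness 150.898; tumor pixels 80
#>   Dice 100.000%, Jaccard 100.000% vs ground truth
#>   brain mask: 1612 px; search: 174 unique evaluations, 846 cache hits
#>   cluster centers: 0.3471 / 0.8553 (2 iterations)
```

The swarm (20 particles, 50 iterations) located the 16×16 block covering
the 80-pixel tumor after evaluating only 174 of the 2401 possible
positions (846 further lookups were cache hits); K-means split the block
at intensity centers 0.35 (tissue) vs 0.86 (tumor), reproducing the
ground-truth mask exactly. `plot(fit)` shows the stripped image, the ROI
and the mask.

The ANOVA building block is exposed directly:

```r
twoway_anova(list(list(c(1, 3), c(2, 4)), list(c(5, 7), c(6, 8))))
#> Two-way fixed-effects ANOVA (a = 2, b = 2, n = 2)
#>          source SS df MS  F         p
#>        factor A 32  1 32 16 0.0161301
#>        factor B  2  1  2  1 0.3739010
#>  interaction AB  0  1  0  0 1.0000000
#>        residual  8  4  2 NA        NA
#>           total 42  7 NA NA        NA
```

A thin command-line front end lives at `inst/cli/swarmseg`
(`phantom`, `preprocess`, `search`, `run`, `evaluate` subcommands), e.g.

```sh
Rscript inst/cli/swarmseg run --diseased d.png --reference r.png \
        --truth gt.png --out results_dir --seed 1
```

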