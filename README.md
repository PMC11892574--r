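# invasionmap

Per-voxel mapping of tumor invasion from diffusion MRI, for
neuroimaging researchers working on glioma margins. Given four
co-registered NIfTI volumes — a white-matter mask, a tumor mask, a
diffusion-tensor field and one or more scalar parametric maps (typically
diffusion-kurtosis metrics such as MK or KA) — the package finds where the
parametric map changes significantly along plausible infiltration routes
through the white matter, and summarizes that per voxel as a percentage
map. Glioblastoma-like infiltration produces strong gradients around (and
beyond) the perifocal zone; purely vasogenic edema, as around metastases,
produces none — that contrast is what the output visualizes.

## Method

1. **Step-distance map.** White-matter voxels are labeled with the minimal
   number of single-voxel steps (26-neighborhood; diagonal steps count 1)
   needed to reach the tumor border while staying inside the white-matter
   mask. Unreachable white matter is excluded.
2. **Transition matrices.** For each eligible voxel *i* and neighbor
   direction *n<sub>ij</sub>*, the directional diffusivity is
   ADC<sub>ij</sub> = *n<sub>ij</sub>*ᵀ D<sub>i</sub> *n<sub>ij</sub>*
   (clamped ≥ 0), and the step probability is
   W<sub>ij</sub> = m<sub>ij</sub>·ADC<sub>ij</sub> / Σ<sub>j</sub>
   m<sub>ij</sub>·ADC<sub>ij</sub>, where the gate m<sub>ij</sub> zeroes
   neighbors outside the mask and those violating the distance rule
   (toward-tumor walks never step to d<sub>j</sub> > d<sub>i</sub>;
   away-walks never to d<sub>j</sub> < d<sub>i</sub>).
3. **Pseudorandom trajectories.** Walks sample these rows until they enter
   a voxel at d = 1; after 12 consecutive steps without approaching the
   tumor the next step is forced downhill. A coverage-driven scheduler
   (starts at d<sub>max</sub> first, then lowest-coverage voxels per
   distance stratum; starts below d<sub>max</sub> are stitched with an
   away-segment) runs until every eligible voxel lies on ≥ 100
   trajectories.
4. **Profiles.** Each trajectory yields the parametric value versus
   distance to the tumor border, smoothed by a 6-sample sliding median;
   local extrema split the profile into monotone segments, significant
   when their amplitude exceeds 3 × 1.4826 × median|raw − smoothed|.
5. **Gradient maps.** Per voxel, Q counts trajectories through it and P
   those with a significant rising (resp. falling) segment covering it;
   the outputs are the rising and falling maps 100·P/Q. "Rising" means
   the parameter increases toward the tumor border.

A synthetic phantom generator (`make_phantom()`,
`make_two_slice_crossing_phantom()`) builds corridor/labyrinth/shell
scenes with planted ground truth, so the whole pipeline is testable
without patient data.

## Worked example

```r
library(invasionmap)
set.seed(1)

# 20^3 labyrinth phantom: glioblastoma-like ramp planted over 5 steps
ph  <- make_phantom(phantom_spec(grid_shape = c(20, 20, 20), seed = 12))
fit <- invasion_map(ph$wm, ph$tumor, ph$tensors, list(MK = ph$pmap),
                    walk = walk_config(seed = 1))
fit
#> Tumor invasion map
#>   grid:          20 x 20 x 20 voxels
#>   eligible WM:   603 voxels, d_max = 21 steps
#>   trajectories:  8835 (min coverage 100, 100 cycles, 0 failed segments)
#>   map MK:      mean up  49.8%, mean down   0.8%
summary(fit)
#> eligible voxels: 603   d_max: 21 steps
#> trajectories: 8835   coverage min/median: 100/115   failed segments: 0
#>  map mean_up_pct max_up_pct mean_down_pct max_down_pct
#>   MK        49.8        100         0.809         18.6
```

Every eligible voxel is crossed by at least 100 trajectories (the
scheduler's termination rule). The rising map averages ~50% here because
the planted ramp — the parameter elevated toward the tumor border, as in
infiltrated white matter — is detected on most trajectories through the
perifocal shell; the falling map stays near zero. Re-running with
`phantom_spec(mode = "metastasis", ...)` (no planted gradient) drives
both maps to a few percent, the false-positive floor of the k = 3
threshold. Write the NIfTI outputs with
`write_invasion_map(fit, "out/")`, or plot a slice with `plot(fit)`.

The same pipeline runs from the shell:

```sh
inst/cli/invasionmap run --wm wm.nii.gz --tumor tumor.nii.gz \
  --tensor dt.nii.gz --pmap mk.nii.gz --out out/ --seed 7
inst/cli/invasionmap phantom --spec spec.yaml --out phantom/
```

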