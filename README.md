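# bulkybone

Why do salamander long bones regrow *bulkier* after amputation than the bones
originally shaped by development? Regenerating skeletal elements stay fully
cartilaginous until they reach their final size, and chondrocytes divide
predominantly transversally — so nothing restrains radial expansion of the
growing rod. During development, by contrast, cortical bone forms in the
mid-shaft while the cartilage is still growing and mechanically blocks
further transversal expansion there, yielding a tapered bone.

`bulkybone` implements this morphomechanical argument as a reproducible
pipeline for researchers in regeneration biology and computational
morphogenesis:

* **Growth simulation** — the bone is a homogeneous linear-elastic cylinder
  (default L = 10 mm, R = 1 mm, E = 1 kPa, ν = 0.40) meshed with structured
  P1 tetrahedra (default 65,664 elements) and loaded by region-specific
  internal body-force densities with axial and radial components
  f = f_a ẑ + f_r r̂. Static equilibrium ∇·σ + f = 0 is assembled and solved
  sparsely; vertices are advected by the displacement field. The
  *regeneration* scenario loads all five axial regions uniformly; the
  *development* scenario ramps the radial moduli down to a fraction c = 0.2
  at the mid-shaft.
* **Shape quantification** — axial diameter profiles, a bulge index
  (mid-shaft over end-band effective radius), signed nominal/actual
  surface-deviation maps with exact point-to-triangle distances, and
  voxel-counting quantification of labeled (micro-CT-segmentation-like)
  volumes.
* **Division-orientation statistics** — axial angles of cell-division
  doublets folded into [0°, 90°], summaries with quartiles and a transversal
  fraction, and Welch or seeded-permutation two-group comparisons.
* **Synthetic data** — seeded generators for doublet sets (truncated-normal
  angles with closed-form moments), labeled volumes of analytic radius
  profiles, and surface pairs with known deviation fields, so the whole
  pipeline runs without any acquisition.
* **IO** — VTU / legacy VTK meshes and heat-map fields (ParaView-ready),
  STL (ASCII + binary) surfaces, NRRD / multi-page TIFF volumes, CSV tables,
  YAML scenarios and run configs. A thin CLI (`exec/bulkybone`) wraps the
  main stages.

See `vignette("bone-shaping")` for the model, its assumptions, parameter
choices and numerical decisions.

## Worked example

```r
library(bulkybone)

# a quick study at reduced resolution (16 x 3 x 12 mesh; ~2 s)
cfg <- run_config(n_axial = 16, n_radial = 3, n_angular = 12, n_bins = 12)
s <- run_pipeline(cfg, "bulkybone-out")

s$bulge_index
#> $regeneration  1.00001
#> $development   0.9851043
#> $ratio         1.015131
s$deviation$peak_axial_fraction
#> 0.5077169
```

With the radial load budget matched between the two scenarios, the uniform
(regeneration) run stays cylindrical (bulge index ≈ 1.000) while the graded
(development) run tapers (0.985): regenerated rods come out relatively
bulkier (ratio 1.015), and the largest outward deviation of the regenerate
over the developed shape sits mid-shaft (axial fraction 0.51), reproducing
the heat-map localization seen in micro-CT shape comparisons. At the default
65k-element resolution the same run takes ~2 minutes and gives ratio ≈ 1.02.

Orientation statistics on synthetic doublets:

```r
d <- gen_doublets(100, mean_angle = 70, sd_angle = 15, seed = 1)
summarize_orientations(doublet_angles(d))
#> Orientation summary: n = 100, mean 68.29 deg, median 67.86
#>   (Q1 61.86, Q3 77.75), sd 11.23
#>   fraction transversal (> 45 deg): 0.980
```

Output artifacts (`mesh.vtu`, `regeneration.vtu`, `development.vtu`,
`deviation.vtu`, `profiles.csv`, `summary.json`) carry provenance stamps
(config hash, seed, package version) and are byte-identical across reruns.

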