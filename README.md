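# tqdf — triple-colour quantitative dynamic footprinting of β2-integrin activation

`tqdf` is an R package for analysing triple-colour quantitative dynamic
footprinting (TqDF) movies: TIRF microscopy of neutrophils rolling and
arresting in a flow chamber, imaged simultaneously in a membrane-dye
channel and two conformation-reporter antibody channels (KIM127 for
integrin ectodomain **e**xtension, mAb24 for headpiece **o**pening).  The
package reconstructs the nanoscale axial geometry of the cell–substrate
contact zone, classifies β2-integrin clusters by conformation, and follows
their activation history through the rolling-to-arrest transition.

## Who it is for

Researchers analysing leukocyte adhesion under flow with qDF/TqDF-style
TIRF data, and method developers who need a fully characterized synthetic
test bed: the package ships a ground-truth scene generator
(`simulate_scene()`, `render_movie()`) that emulates membrane topography
over microvilli, cluster placement, two-pathway conformational kinetics,
rolling/arrest motion and camera noise, so every analysis stage can be
validated against known truth.

## The model in brief

**Height mapping.** Under total internal reflection the evanescent
excitation decays as `I(Δ) = I0·exp(−Δ/d)` with penetration depth
`d = λ / (4π √(n₁² sin²θ − n₂²))` (≈79.9 nm for 488 nm at θ = 70°,
n₁ = 1.515, n₂ = 1.338).  Membrane-channel intensity therefore inverts to
a per-pixel height above the coverslip, `Δ = d·ln(I0 / (I − background))`,
trusted within ~200 nm.  The cell *footprint* is the region with
Δ ≤ 95 nm; *hills* (microvillus tips) and *valleys* partition the
footprint by a two-class threshold on Δ.

**Conformational classes.** Pixels positive for KIM127 only are E+H−
(extended, closed headpiece), for mAb24 only E−H+ (bent-open, the
cis-interacting state), for both E+H+ (fully activated).  Clusters are
connected components above their local background; transitions follow the
two allowed activation pathways E−H− → E+H− → E+H+ and
E−H− → E−H+ → E+H+.

**Functional readouts.** Cell velocity from footprint centroids with
arrest at < 0.1 µm/s; clusters "within reach" of trans ligand at
Δ ≤ 50 nm; antibody binding sites via linear bead calibration; FRET
efficiency `E = 1 − F′_D/F_D`, overlap integral
`J = ∫F_D ε_A λ⁴ dλ / ∫F_D dλ`, Förster radius
`R0 = 0.02108·(κ² Q_D η⁻⁴ J)^(1/6)` nm and donor–acceptor distance
`r = R0·((1−E)/E)^(1/6)`.

## Worked example

Simulate the default scene (a neutrophil rolling at 1 µm/s into a
64×64-px field, arresting at t = 0 with 9/9/3 E+H−/E−H+/E+H+ clusters at
scene start), render it with shot noise, and analyse the arrest frame:

```r
library(tqdf)

opt <- optical_config()
d <- penetration_depth(opt, "membrane")   # 104.9 nm at 641 nm

scene <- simulate_scene(scene_config(rng_seed = 7))
movie <- render_movie(scene)

est  <- estimate_reference_intensity(movie[, , "membrane", 31])
hm   <- intensity_to_height(movie[, , "membrane", 31], est$i0, d, est$background)
fp   <- footprint_mask(hm, min_px = 50)
topo <- segment_hills_valleys(hm, fp)
kim  <- segment_clusters(movie[, , "kim127", 31], fp)
mab  <- segment_clusters(movie[, , "mab24", 31], fp)
conf <- classify_pixels(kim > 0, mab > 0)
summarize_classes(conf)
#>   class n_clusters total_area_px mean_size_px
#> 1  E+H-          0             0           NA
#> 2  E-H+          2            57     28.50000
#> 3  E+H+         19           547     28.78947
```

The footprint covers 3062 px (12.5 µm²) of which 27.2% are hills,
matching the generator's 27% target; the recovered class counts equal the
scene's ground truth at arrest (0/2/19).  Localizing clusters against the
height map counts those able to engage ICAM-1 in trans:

```r
loc <- localize_clusters(label_components(unclass(conf) > 0, 8),
                         topo, hm, conf_map = conf)
count_within_reach(cbind(loc, frame = 31))
#>   frame class n_within_reach
#> 1    31  E-H+              0
#> 2    31  E+H+             11
```

FRET machinery on the bundled synthetic spectra:

```r
r0 <- forster_radius(overlap_integral(synthetic_fret_spectra()))
fret_distance(0.3, r0)
#> toy-spectra Forster radius: 5.49 nm; r at E = 0.3: 6.32 nm
```

`run_pipeline(pipeline_config(seed = 7), "out/")` executes the whole
chain — simulate → heights → segment → classify → track → localize →
quantify — and writes CSV tables (class summaries, cell track, transition
history, localization, reach counts, summary scalars), TIFF stacks, the
effective configuration and a provenance record into `out/`.

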