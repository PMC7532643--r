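# vesselex

Quantification of perivascular antibody extravasation in two-channel
confocal fluorescence microscopy.

## The problem

Antibody therapies against solid tumors are limited by poor penetration of
the drug beyond the vessel wall. Studies of vascular-permeabilization
interventions (for example ultrasound-targeted microbubble cavitation)
evaluate their effect vessel by vessel on tumor sections: a nuclear
perfusion stain marks the vasculature in one channel, and a fluorescently
labeled antibody is imaged in a second channel. vesselex turns such image
pairs into per-vessel extravasation metrics and group-level statistics, for
researchers who need that quantification to be reproducible and testable.

## The method

For each field, vessels are segmented from the nuclear channel (Otsu
threshold → isolated-pixel removal → 8 µm disk dilation defining the vessel
*inside* → a further 25 µm dilation merging nucleus agglomerations), and a
watershed on the negated Euclidean distance transform assigns every pixel to
the influence zone of its nearest vessel. Within the zone of vessel *k*, with
inside integral *I*<sub>in</sub> of the noise-masked antibody signal and
cumulative outside integral *O*(*d*) up to distance *d* from the vessel,

&nbsp;&nbsp;&nbsp;&nbsp;ΔAb(*d*) = *O*(*d*) − *I*<sub>in</sub>

is the cumulative differential extravasated antibody signal. Each vessel is
summarized by [ΔAb]<sub>max</sub> = max<sub>d</sub> ΔAb(*d*), by its
**extravasation range** (the smallest *d* attaining that maximum), and by the
classification **extravasated** iff [ΔAb]<sub>max</sub> > 0. Sides of a
paired design are compared by Fisher's exact test on the
extravasated/not-extravasated contingency table, and by two-way ANOVA with
Fisher LSD or Šidák post-hoc tests on [ΔAb]<sub>max</sub> and range. A
synthetic field generator with per-vessel ground truth (straight vessels,
nucleus-lined walls, exponential perivascular halos of decay length λ)
supports end-to-end validation by parameter recovery.

## Worked example

```r
library(vesselex)

cfg <- simulation_config(image_height_px = 768L, image_width_px = 768L,
                         n_vessels = 10L, seed = 7)
field <- generate_field(cfg)
seg <- segment_vessels(field$blue)
profiles <- profile_all(seg, field$red)
profiles
#> <vessel_profiles> 10 vessels, 5 extravasated (50%)
head(profiles_table(profiles), 4)
#>   vessel_id delta_ab_max extravasation_range_um extravasated
#> 1         1    -67209.36                      2        FALSE
#> 2         2    456532.92                     42         TRUE
#> 3         3    467966.99                     41         TRUE
#> 4         4    -68517.10                      0        FALSE

map <- match_ground_truth(seg, field$truth)
mean(profiles_table(profiles)$extravasated[map] == field$truth$vessels$leaky)
#> [1] 1
```

Ten vessels are segmented from the simulated stain; the five leaky ones show
large positive [ΔAb]<sub>max</sub> (more antibody outside than inside, with
ranges of ~40 µm at the default λ = 30 µm halo), the five tight ones are
negative, and the classification matches the simulated ground truth exactly.

Group comparison on published-style contingency counts:

```r
fisher_exact_2x2(contingency_table(27, 32, 46, 18))
#> [1] 0.003610276
```

File-based runs use `read_field()`/`run_pipeline()` on multi-channel TIFFs
(CSV and JSON-manifest outputs), or the thin command-line front end in
`inst/cli/vesselex` (`simulate` and `run` subcommands).

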