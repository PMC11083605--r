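# boluscope

Quantitative comparison of in vivo and in vitro mastication of soft
foods, and selection of chewing-simulator (masticator) settings that
reproduce human chewing — for food oral-processing researchers working
with products too soft and sticky for sieve-based bolus analysis.

A soft cheese is surface-coloured so that chewing mixes a coloured and an
uncoloured phase; the homogeneity of a bolus photographed on a green
backdrop is scored by the **population variance of the red channel**
inside the bolus region (higher variance = less mixed),

    V = (1/|Ω|) Σ_{i∈Ω} (x_i − x̄)²,  x_i ∈ [0, 1],

and its texture by the **final charge**: the force (N) at the end of a
back-extrusion travel. In vivo masticatory parameters (mouth volume,
quantity consumed, mastication time, tongue–palate compressions, saliva
volume from the bolus/cheese moisture balance) are transposed to a
masticator — cheese load = container volume / (mouth volume / quantity
ratio), saliva schedule = rate × pieces × compressions — and every
group × stage measurement is matched to the nearest in vitro operating
point on a compressions × rotation-speed grid. Supporting inference:
CIELAB ΔE colorimetry, split-plot (mixed-design) ANOVA with Type III
partitioning, and the exact binomial triangle test. A synthetic-data
module generates panels, two-phase mixing images and force curves with
the statistical structure the analysis assumes.

## Worked example

```r
library(boluscope)

# Colour control: is the surface colouring visible?
cols <- reference_lab_colors()
de <- delta_e(cols$uncolored, cols$colored)
round(de, 2)                       # 42.24
is_visually_distinct(de)           # TRUE  (threshold ΔE > 5)

# Transpose the pooled panel means to the masticator
in_vitro_cheese_mass(masticator_config(), 11.47)   # 32.69 g
in_vitro_saliva_volume(0.05, 7, c(1, 18))          # 0.35 mL, 6.30 mL

# Match in vivo stage measurements to the nearest in vitro settings
res <- match_all(reference_invivo_measurements(),
                 reference_invitro_measurements())
res$recommendation
#>   group n_compressions rotation_speed
#> 1 child              6              4
#> 2 adult             14             15
```

The recommendation reads: chewing of the cheese by children up to the
swallowing point is best reproduced by 6 plunger compressions at 4 rpm;
adult chewing needs 14 compressions at 15 rpm (adults chew longer and mix
more). An end-to-end synthetic run — panel → images → curves → ANOVA →
matching, written as CSVs plus a manifest — is one call:

```r
res <- run_pipeline(run_config(seed = 1, out_dir = "run"))
```

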