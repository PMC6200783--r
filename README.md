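# choroidflow

Visualize and quantify **middle/large choroidal blood flow** in
swept-source OCT angiography (OCTA) by removing the choriocapillaris
projection artifact from a half-choroid en-face slab.

In normal eyes the mid-choroid OCTA slab looks inverted: vessel lumina
are dark and the stroma is white, because flow in the choriocapillaris
(the capillary layer just under the RPE) projects onto the tissue below
it. `choroidflow` removes that artifact with a three-step saturating
subtraction of the choriocapillaris slab (CC) from the half-choroid slab
(HC), whose closed form per 8-bit pixel is

```
final = min(max(CC − HC, 0), HC)
```

so pure stromal projection (`CC ≤ HC`) maps to 0 and strongly contrasted
lumina (`CC ≥ 2·HC`) keep their full flow signal. The artifact-free
image is binarized with Bernsen's auto local threshold (circular
neighbourhood, low-contrast fallback), the optic disc is excluded with
an elliptical mask on wide-field scans, and the **flow-area ratio** (%
of flow pixels) is correlated with subfoveal choroidal thickness (SCT)
by Spearman rank correlation. The package also ships:

* slab geometry anchored on the outer RPE surface (CC slab 30–60 µm
  below the RPE; HC slab 30 µm wide centred at SCT/2), SCT measurement,
  and the < 150 µm eligibility filter;
* the packaged 61-eye normal cohort table (`cohort_table1()`) and its
  summary statistics;
* a synthetic phantom generator (uniform choriocapillaris, random-walk
  vessel tubes, proportional stromal artifact, additive noise, and a
  spectral-domain attenuation mode) with ground-truth lumen masks;
* a command-line interface (`inst/cli/choroidflow`) with subcommands
  `extract-slabs`, `subtract`, `quantify`, `cohort-stats`, `simulate`.

## Worked example

```r
library(choroidflow)

# A phantom eye with known ground truth (25% vessel coverage)
ph <- render_phantom(phantom_params(seed = 3))
q  <- quantify_eye(ph$cc, ph$hc)
q
#> <flow_ratio> 26.6% (9814 / 36864 px analyzed)
dice_coefficient(q$flow_mask, ph$truth$lumen_mask)
#> [1] 0.9714944

# The packaged normal cohort
summarize_cohort(filter_eligible(cohort_table1()))
#> <cohort_summary> 61 eyes of 45 cases
#>   age (per case, years): 38.5 +/- 8.0 (range 26-67)
#>   SCT (um):              298.0 +/- 61.7 (range 180-500)
#>   flow area (%):         27.3 +/- 8.2 (range 11.5-50.1)
#>   Spearman rho(SCT, flow) = 0.735, p = 1.6e-11
```

The phantom's measured ratio (26.6 %) recovers its true 25.1 % lumen
coverage to within the binarization's boundary error, and the Dice
overlap with the ground-truth mask is 0.97. On the clinical table, the
flow-area ratio rises strongly with choroidal thickness
(rho = 0.735, p ≪ 0.01). From a shell:

```sh
Rscript inst/cli/choroidflow quantify --cc cc.tif --hc hc.tif --out report.json
Rscript inst/cli/choroidflow cohort-stats --table table1.csv --out summary.json
```

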