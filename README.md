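# chromoscore

Quantitative staining-quality scores for gastric chromoendoscopy images,
and a pipeline that finds the dye concentration maximizing them.

In chromoendoscopy a dye is applied to the stomach mucosa to enhance
visibility: a contrast dye (indigo carmine) pools in depressed early-cancer
lesions, an absorptive stain (methylene blue) highlights overall mucosal
texture. Visibility rises with concentration up to an optimum and collapses
when the tissue oversaturates. `chromoscore` provides the two image scores
used to locate that optimum on a concentration series of tissue-patch
photographs, plus a synthetic patch generator so the whole workflow runs
without access to the original photographs.

**Lesion-to-background contrast.** For annotated lesion and healthy
regions `R_l`, `R_h` of a grayscale image,

    I_c = g(R_l) − g(R_h)

with `g` the mean gray value of a region (|I_c| ≤ 255 on 8-bit images; the
absolute value is reported by default, the signed value retained).

**Global texture variance.** Around each pixel, N = 8 intensities are
sampled on a circle of radius R (the local-binary-pattern neighborhood;
off-grid positions bilinearly interpolated) and their population variance

    var(R,N)(c_x, c_y) = (1/N) Σᵢ (p_n(i) − μ)²,   μ = (1/N) Σᵢ p_n(i)

is averaged over all centers whose circle fits in the image, then over
radii R = 10, 20, 30, 40, 50 px, giving the mucosa-visibility score
`var(R,N)_g`.

The pipeline averages replicate patches per concentration, takes the grid
argmax of the mean score as the optimal concentration (ties broken toward
less dye), and reports the percent increase of the peak over unstained
tissue.

## Worked example

Generate a small synthetic indigo-carmine concentration series (two
replicate lesion-bearing 256×256 patches per concentration and stomach
region), score it, and locate the optimum:

```r
library(chromoscore)

design   <- indigo_design(replicates = 2L)
records  <- generate_design(design, master_seed = 7)
analysis <- run_pipeline(records, design)
analysis
#> Concentration analysis: 36 patches, 2 arms
#>   indigo_carmine / fundus (contrast): optimum 0.2% (mean score 68.834), +390.2% over unstained
#>   indigo_carmine / pylorus (contrast): optimum 0.6% (mean score 36.698), +204.1% over unstained

head(analysis$arms[["indigo_carmine.fundus"]]$summary, 4)
#>   concentration mean_score  sd_score n
#> 1           0.0   14.04315 1.4065380 2
#> 2           0.2   68.83445 1.6437280 2
#> 3           0.4   45.10301 0.3629348 2
#> 4           0.6   20.05847 0.1609077 2
```

The fundus arm peaks at 0.2 % dye and the pylorus arm at 0.6 % — the
region-dependent optima planted by the default synthetic dose-response
model (`default_stain_model()`). Each mean is the average contrast score
over the replicate patches at that concentration; the percent increase
compares the peak against the unstained (0 %) baseline of the same arm.
A single patch can be scored directly:

```r
p <- records[[2]]                       # an unstained fundus patch
contrast_score(p$image, p$regions)
#> Lesion-to-background contrast I_c = 13.049 (lesion 157.233, healthy 170.282, absolute)
```

`multi_radius_score(img)` gives the texture score of an image, and
`run_pipeline()` also accepts a manifest CSV pointing at PNG/TIFF images
and JSON region annotations on disk (see `generate_design(..., dir =)` and
`inst/scripts/chromoscore` for the command-line front end with
`simulate` / `score` / `analyze` / `all` subcommands).

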