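# fibromat

Computer-based morphometry of liver fibrosis in Sirius Red–stained
micrographs.

Sirius Red stains collagen fibres and cell nuclei red while the
hepatocellular cytoplasm stays pale and yellowish, so the green colour
channel separates stained from unstained tissue. `fibromat` turns that
contrast into a reproducible measurement — the **fibrosis index**, the
collagen proportionate area of a field:

```
index = fibre area / parenchyma area        (0.00 – 1.00, i.e. 0 – 100 %)
```

where the parenchyma is every non-background, non-excluded tissue pixel
(fibres included) and bright vessel lumina and slide background are
excluded automatically. The package is aimed at experimental hepatology
workflows (e.g. bile-duct-ligation time courses in mice) where fibrosis is
otherwise graded semi-quantitatively by a pathologist: it computes the
index per micrograph, aggregates ten random high-power fields per liver
into a per-animal index, summarizes groups as mean ± SEM, and regresses
the index against a two-tiered semi-quantitative score (periportal 0–4,
perisinusoidal 0–2, total 0–6).

## The pipeline

For each 24-bit RGB field (BMP, PNG or TIFF):

1. grey transform from the **green channel** only (red stain absorbs green);
2. **shading correction** by robust (windowed-median) flat-field division;
3. **arithmetic mean filter** (5 × 5 at the 1280 × 1024 reference
   resolution) for noise suppression;
4. background/lumen exclusion by **brightness cutoff** (grey ≥ 240);
5. **automatic threshold** from a histogram analysis of the tissue grey
   values: Otsu's between-class-variance split, cut placed at the
   intermeans midpoint, plus a user offset for staining-intensity
   differences;
6. binarization of the dark (stained) class;
7. **binary object detection** and elimination of objects smaller than
   200 px (reference resolution) — nuclei stain like fibres but are far
   smaller;
8. optional **exclusions** (object ids or mask regions; removed from
   numerator *and* denominator);
9. the index, plus a verification overlay (background black, parenchyma
   light green, fibres red).

Everything is deterministic, configurable through `morphometry_config()`,
and validated end-to-end against a built-in synthetic field generator with
ground-truth masks (`synthesize_field()`), since no study images are
distributed.

## Worked example

```r
library(fibromat)

# a synthetic 1280x1024 field with 4.75% planted tissue collagen fraction
fld <- synthesize_field(synthetic_spec(collagen_fraction = 0.0475, seed = 1))
fld
#> <synthetic_field 1280x1024 planted 0.0475 realized 0.0475 seed 1>

analyze_field(fld$image, id = "demo_field")
#> <field_result demo_field 1280x1024>
#>   fibrosis index: 0.0465 (4.65%)
#>   fibre 58413 / parenchyma 1256847 px; background 53873; excluded 0; threshold 129.743
```

The planted 4.75 % fraction is recovered as 4.65 % — the fibre area is
measured from the thresholded image, the parenchyma excludes the bright
lumen discs (the 53 873 background pixels), and the automatic threshold
settled at grey-level ~130, halfway between the stained (~60) and
unstained (~200) green-channel modes. Over several fields:

```r
idx <- vapply(1:3, function(i) {
  f <- synthesize_field(synthetic_spec(0.0475, seed = i))
  analyze_field(f$image)$fibrosis_index
}, numeric(1))
round(idx, 4)
#> [1] 0.0465 0.0470 0.0467

group_summary(100 * idx, label = "day 14-like")
#> <group_summary day 14-like n=3 4.67 +/- 0.02>

linear_fit(c(0, 1, 3, 4, 6), c(0.0012, 0.0101, 0.0297, 0.0404, 0.0589))
#> <regression_result y = 0.0097 x + 0.0009, R^2 = 1.000, n = 5>
```

## Command line

The installed script `cli/fibromat.R` (see
`system.file("cli", "fibromat.R", package = "fibromat")`) exposes batch
analysis without writing R:

```sh
fibromat synth   --fraction 0.02 --n 5 --seed 7 --out fields/
fibromat analyze --out run/ --overlay fields/field_*.png
fibromat correlate --indices run/indices.tsv --scores scores.csv
fibromat summarize --indices indices_by_group.tsv --scores scores.csv
fibromat session show run/session.fibromat.json
```

`analyze` writes a tab-separated index export (4 decimal places, ready
for any statistics package), a resumable `.fibromat.json` session file
with content checksums (so a collaborator is warned if an image changed),
and optional overlays. Exit status is 0 on success, 1 if any field
failed, 2 for usage errors.

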