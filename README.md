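# srin — spatial RNA integrity scoring from sequential probe images

Bulk RNA integrity numbers (RIN) summarize a whole tissue lysate in one
number, so a specimen with pristine tumor tissue next to a necrotic core can
look mediocre overall while hiding both extremes. `srin` computes a
**spatial** RNA integrity number: a per-pixel 0–10 score of 18S rRNA
completeness over a tissue section, from five fluorescence scans of a
capture slide — a background autofluorescence scan (P0) taken before any
probe, and four scans (P1–P4) after sequentially hybridizing probes at
increasing distance from the capture site along the surface-bound c18RNA
footprint. Degraded RNA produces short footprints that distal probes cannot
reach, so the probe ladder reads out fragment length pixel by pixel.

The package is aimed at spatial-transcriptomics labs triaging sections
before committing to costly downstream assays, and at anyone validating the
scoring logic itself: it ships a synthetic tissue simulator so the whole
pipeline can be exercised end-to-end without wet-lab data.

## The score

For a user-set quantile `q` (default 0.75; 0.30 for low-RNA tissues), the
signal-to-noise threshold is `T = quantile(P0, q)`. The normalization field
is

```
N(x,y) = P1(x,y) − P0(x,y) − T
```

with pixels `N ≤ 0` masked as no-signal. Each probe is normalized as
`R_i = (P_i − P0 − T) / N` (so `R1 ≡ 1`), and the score is

```
sRIN(x,y) = 2.5 · Σ_{i=1..4} clip(R_i, 0, 1)   ∈ [2.5, 10] on valid pixels
```

— each fully detected probe contributes 2.5 points: 10 means all four
probes detected (intact RNA), 7.5 three probes, 5 or less at most two. The
unclipped sum cannot exceed 10 under correct registration, so pixels with a
raw sum above 10 are flagged as inter-round misalignment, excluded from
summaries, and tested for spatial uniformity with a chi-square diagnostic
(clustered flags mean the scans need re-alignment).

## Worked example

```r
library(srin)

# a degraded-tissue phantom, rendered to a five-round stack
ph  <- make_phantom(c(128L, 128L), profile = "patchy", mu = 2000, seed = 1)
sim <- render_stack(ph, seed = 2)
map <- compute_srin(sim$stack, q = 0.75)
map
#> <srin_map: 128 x 128 px, 7056 valid (43.1%), 77 misaligned, q=0.75, T=4400>

detect_misalignment(map)
#> <misalignment_report: 1.091% of valid pixels flagged; chi-square 19.90 on 12 df, p = 0.0691>

summarize_sample(list(map))
#> <sample_summary: averaged sRIN 5.000 over 1 replicate(s)>

render_heatmap(map, "srin_heatmap.png")   # fixed 0-10 color scale
```

About 43% of pixels carry tissue signal; the ~1% of pixels whose raw score
exceeds 10 show no significant spatial clustering (uniformity p = 0.07, no
re-alignment needed), and the section's median integrity is 5.0 —
consistent with its 2000-nt mean fragment length, which lets most
footprints reach probes 1–2 but few reach probes 3–4.

The same pipeline runs from the shell:

```sh
inst/scripts/srin simulate --preset single --seed 1 --out sim/
inst/scripts/srin compute --p0 sim/p0.tif --p1 sim/p1.tif --p2 sim/p2.tif \
    --p3 sim/p3.tif --p4 sim/p4.tif --q 0.75 --out out/
```

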