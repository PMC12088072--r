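# fusemd

Multimodal medical image fusion for co-registered MRI and PET slices, with
the standard objective fusion-quality metrics and a synthetic phantom
generator, as an R package with a command-line front end.

In oncology imaging, MRI carries high-resolution anatomical structure and
PET carries functional (metabolic) information at low spatial resolution.
Fusing the two into one image aids diagnosis, but naive fusion blurs edges
and loses fine detail. `fusemd` implements a transform-domain fusion chain
that processes structure and trend separately:

1. **Band split (Laplacian pyramid).** Each source X is decomposed into two
   high-frequency sub-bands and a low-frequency sub-band,
   `LP(X) -> [HX1, HX2, LX]`.  The default is an undecimated
   difference-of-Gaussians stack (`h1 = X - G1(X)`, `h2 = G1(X) - G2(X)`,
   `low = G2(X)`), so `h1 + h2 + low = X` exactly; a classic decimated
   Burt–Adelson pyramid is available behind a flag.
2. **Bidimensional EMD.** Every high band is sifted into two intrinsic mode
   functions and a residue, `EMD(H) -> [IMF1, IMF2, RES]`, with
   `IMF1 + IMF2 + RES = H` exact by construction.  Envelopes are built by
   nearest-extremum filling plus Gaussian smoothing; sifting stops on a
   Cauchy-type criterion.
3. **Rolling guidance filtering.** The IMFs are denoised by a Gaussian
   pre-filter followed by iterated joint bilateral filtering (range weights
   on the previous iterate), which suppresses small-scale incoherent
   oscillation while recovering coherent edges.
4. **Phase-congruency fusion.** Corresponding IMFs of the two modalities
   are fused by per-pixel selection: the pixel comes from whichever IMF has
   the larger phase congruency (a log-Gabor measure of local phase
   agreement, high on edges and lines regardless of contrast polarity);
   ties take the mean.  Residues and the low bands are mean-fused.
5. **Recombination.** The fused components are summed (undecimated) or
   recombined through the pyramid (decimated), giving the fused image F.
   Color PET input is handled by fusing the MRI with the PET *luma* and
   re-attaching the PET chroma afterwards.

Fusion quality is scored by eight standard measures: entropy (EN), fusion
PSNR, fusion mutual information (MI), average gradient (AG), fusion SSIM,
and the Xydeas–Petrović edge-information triple QABF (preserved), LABF
(lost), NABF (spurious), which partitions total edge information and sums
to 1.

Because public MRI–PET pairs cannot be bundled, the package generates
co-registered synthetic phantoms: shared nested-ellipse anatomy, MRI-only
fine texture, PET-only smooth hotspots rendered through a pseudo-color
map, independent noise per modality, all driven by one seed.

## Worked example

```r
library(fusemd)

spec <- phantom_spec(seed = 42)          # 128x128 pair, fixed by the seed
pair <- generate_phantom_pair(spec)

res <- fuse_images(pair$mri, pair$pet)   # full method, default config
res
#> Fused image 128x128, range [0.000, 1.000]

metric_report(res$fused, pair$mri, pair$pet_luma)
#> Fusion quality metrics:
#>      en    psnr      mi      ag    qabf    ssim    labf    nabf
#>  6.8820 18.2272  5.1439 12.2980  0.5050  0.6816  0.3824  0.1126
```

Half the source edge information survives fusion (QABF 0.50 against 0.43
for plain averaging of these phantoms), the fused image stays structurally
close to both sources (SSIM 0.68), and the edge triple sums to one.
`res$fused_color` holds the re-colorized fused image; `save_image()` writes
any result to PNG/TIFF/JPEG.

The component stages are exported individually (`lp_decompose()`,
`bemd2()`, `phase_congruency()`, `rolling_guidance()`, `pc_fuse()`,
`mean_fuse()`), and `ablation_study(n_pairs, seed)` reproduces the
four-phase ablation (LP+mean / +EMD / +PC / +RGF) as a per-phase mean
metric table.

## Command line

```sh
exec/fusemd phantom  --out-dir data --seed 7
exec/fusemd fuse     --mri data/phantom_mri.png --pet data/phantom_pet.png --out fused.png
exec/fusemd metrics  --fused fused.png --mri data/phantom_mri.png --pet data/phantom_pet.png --out scores.csv
exec/fusemd ablation --n-pairs 5 --seed 7 --out ablation.csv
```

Every run writes a JSON manifest (inputs, effective configuration, seed,
tool version) beside its outputs; re-running from the same manifest
reproduces outputs bitwise.

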