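# pepatlas

Single-cell neuropeptide atlases from MALDI mass spectrometry imaging (MSI).

## The problem

MALDI-MSI detects dozens of neuropeptides in parallel on a tissue section,
but its ~20 µm pixels are coarser than the 5–14 µm neurons of small
invertebrate ganglia, so an ion image alone cannot say *which cell* a peptide
comes from. `pepatlas` implements the complementary strategy: co-acquired
fluorescence microscopy of transgenically labeled peptidergic cells provides
the single-cell reference layer, the MSI ion images are registered onto the
microscopy grid by a rigid transform with bilinear (linear-interpolation)
resampling, and each peptide's signal is masked to the segmented cells. The
resulting per-peptide, per-section *mapping images* are the atoms from which
2D atlases, serial-section colocalization statistics and 3D STL atlases are
built.

The package is aimed at labs doing on-tissue single-cell peptidomics of
small organs (ascidian cerebral ganglia and similar), and at anyone who
needs a scriptable, tested reimplementation of this integration workflow.

## What it computes

* **Peptide bookkeeping** — monoisotopic [M+zH]ᶻ⁺ masses, b/y fragment ions
  and ppm-tolerance MS/MS matching:
  m/z = (Σ residues + H₂O + Σ mods + z·1.007276)/z.
* **MSI I/O** — imzML 1.1 + ibd reading/writing (continuous and processed),
  per-spectrum TIC normalization, ion-image extraction over an inclusive
  ±tolerance window, average spectra.
* **Registration** — percentile auto-contrast 8-bit conversion,
  rolling-ball / sliding-paraboloid background subtraction (grayscale
  opening), rigid resampling `p_fixed = R(θ)·s·p_moving + (dx,dy)` with
  bilinear interpolation, and NCC grid-search transform estimation.
* **Cell mapping** — Otsu segmentation with a 5–14 µm equivalent-diameter
  filter, integration of ion images onto cells, pseudocolor composites,
  multi-page TIFF layer stacks.
* **Colocalization** — 16-bit promotion (×257), intermodes or fixed
  8400–65535 binarization, and pooled-area statistics over section stacks:

  Tanimoto = Overlap / (Areaₐ + Area_b − Overlap),  M1 = Overlap / Areaₐ,
  M2 = Overlap / Area_b

  with the exact identity 1/T = 1/M1 + 1/M2 − 1, plus pairwise heatmaps.
* **3D atlas** — section stacking into voxel volumes (10 µm z-pitch),
  marching-tetrahedra isosurfaces, binary/ASCII STL export
  (84 + 50·n bytes binary layout) and a JSON scene manifest.
* **Synthetic phantoms** — whole-ganglion ground truth (36 sections ×
  50 cells, three expression domains, known transform and noise) rendered
  both as fluorescence images and as imzML MSI datasets, used to validate
  every stage end to end.

## Worked example

```r
library(pepatlas)

cfg   <- phantom_config(seed = 1, n_sections = 4, cells_per_section = 30,
                        semiaxes = c(x = 200, y = 140))
truth <- generate_phantom(cfg)
pipe  <- run_phantom_pipeline(truth)   # render -> segment -> register -> map
cm    <- coloc_matrix(pipe$stacks)
round(cm$tanimoto, 2)
```

```
          pep-TK pep-CCK pep-NT pep-LFa pep-LFb pep-bcast
pep-TK      1.00    0.34   0.50    0.07    0.08      0.37
pep-CCK     0.34    1.00   0.11    0.04    0.04      0.19
pep-NT      0.50    0.11   1.00    0.09    0.11      0.31
pep-LFa     0.07    0.04   0.09    1.00    0.90      0.33
pep-LFb     0.08    0.04   0.11    0.90    1.00      0.35
pep-bcast   0.37    0.19   0.31    0.33    0.35      1.00
```

The co-expressed ventral pair (`pep-LFa`/`pep-LFb`, coupled with probability
0.9 in the generator) stands out at Tanimoto 0.90 — close to its ground
truth of 0.94 from `truth_coloc(truth, "pep-LFa", "pep-LFb")` — far above
every independently drawn pair; channels sharing a spatial domain sit near
0.3–0.5 and channels from disjoint domains below 0.1. Continue to 3D with:

```r
vol  <- assemble_volume(lapply(pipe$stacks[["pep-TK"]], function(m) m$grid))
mesh <- volume_to_mesh(vol)
write_stl(mesh, "pep-TK.stl")
```

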