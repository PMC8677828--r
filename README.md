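# edgeup

Model-based 3D edge enhancement with 2× super-resolution upsampling for
small, low-contrast structures in volumetric MRI — built for
subcortical nuclei such as the lateral geniculate nucleus (LGN) on
routine 0.8 mm T1-weighted scans, where partial-volume mixing at the
boundary makes the measurable volume of a ~176 mm³ structure anything
between 110.6 and 262.1 mm³.

**Who it is for:** researchers doing small-structure volumetry on
clinical-quality 3D scans, who need a sharp, upsampled boundary for
delineation without a high-field scanner, long acquisitions, or a
training dataset.

## The method

The local boundary of a small structure is modelled as a piece of a
polyhedron: faces, edges and vertices are represented by binary
templates built from 1, 2 or 3 intersecting half-spaces on a 6×6×6 grid
at doubled resolution, downsampled to 3×3×3 by exact block means. Every
voxel's 3×3×3 neighbourhood *I* is fitted against each template *E*
with the affine model *I* ≈ *K·E* + *B*, using the closed form

```
K = Σ E·(I − ⟨I⟩) / Σ E·(E − ⟨E⟩),   B = ⟨I⟩ − K·⟨E⟩,
SSR = Σ (I − K·E − B)²
```

The template with minimal SSR (found with an exactly equivalent
matched-filter matrix product) supplies its high-resolution central
2×2×2 block, scaled by (*K*, *B*), as the voxel's replacement — the
output grid is 2× finer (0.8 → 0.4 mm). Between detection passes the
image is noise-averaged on a one-voxel-shifted 2×2×2 partition and
re-registered to the original grid, which leaves detected edges in
place; detection and averaging are iterated (3 passes by default,
6+ for very noisy data).

Validation is built in: an exactly rasterized cube phantom (5.6 mm =
7 voxels, volume 175.616 mm³, half-voxel offset so every face has
partial-volume voxels) with seeded Gaussian noise, automated
half-maximum segmentation, and Dice/volume scoring
(DSC = 2·V_shared / (V_cube + V_delineation)) against the exact
high-resolution ground truth.

## Worked example

Enhance a noisy synthetic phantom and score it (this is the σ = 1/2,
CNR = 2 condition — noise SD half the object contrast):

```r
library(edgeup)
lib <- build_unit_library()        # ~1 s
print(lib)
#> Edge template library: 23232 units (1-plane 102, 2-plane 1294, 3-plane 21836)
#>   normals: principal directions | offset spacing: 1 | variance cutoffs: 0.1875/0.1094

spec  <- phantom_spec()                       # 5.6 mm cube in a 22^3 ROI at 0.8 mm
noisy <- add_gaussian_noise(rasterize_cube(spec), sigma = 0.5, seed = 7)
enh   <- enhance(noisy, lib, n_iterations = 6)
print(enh)
#> volume_grid: 44 x 44 x 44 voxels @ 0.4 mm (high resolution)
#>   intensity range [-0.9893, 2.086], origin (0.20, 0.20, 0.20) mm

seg   <- segment_halfmax(enh)
truth <- ground_truth_mask(spec, grid = enh)
sprintf("volume: %.1f mm^3 (truth %.3f), DSC: %.3f",
        mask_volume(seg), mask_volume(truth), dice_coefficient(truth, seg))
#> "volume: 189.2 mm^3 (truth 175.616), DSC: 0.938"
```

A single replicate fluctuates; averaged over seeded replicates the
σ = 1/2 condition recovers the volume within a few mm³ and a Dice
overlap in the mid-90s% (see below). Without enhancement the same
noisy volume cannot be thresholded meaningfully at all.

On real data the workflow is: `read_volume()` a NIfTI scan,
`extract_roi()` a 22³ box around a seed voxel found visually,
`enhance()` with 3 iterations, `write_enhanced()` — the output overlays
the input in world coordinates at 0.4 mm. The same steps are available
from the shell:

```sh
inst/cli/edgeup build-library --out lib.json
inst/cli/edgeup enhance --in T1.nii.gz --center 97,115,77 --roi 22 \
    --library lib.json --iterations 3 --out lgn_enh.nii.gz
inst/cli/edgeup phantom-validate --library lib.json --out results/
```

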