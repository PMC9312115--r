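# imatq

Quantification of intramuscular adipose tissue (IMAT) in quantitative MRI of
the lower limb.

In muscular dystrophies such as dysferlinopathy and Charcot–Marie–Tooth
disease, fat progressively infiltrates the muscle compartment, and the share
of the muscle that has turned to fat is a biomarker of disease severity.
`imatq` implements a two-stage analysis of multi-echo spin-echo (MESE) MRI
that produces this biomarker automatically:

1. **Quantitative mapping.** Per-pixel T2 and proton density (PD) are
   estimated by matching each measured echo-decay curve against a
   precalculated dictionary of extended-phase-graph (EPG) simulations over a
   (T2, B1+) grid — the dictionary approach handles the stimulated echoes
   that corrupt naive exponential fitting of MESE data. A two-compartment
   water/fat decomposition then yields a sub-pixel fat fraction
   ff ∈ [0, 1], and pixels with ff > 50% define the IMAT reference labels.
2. **Segmentation and clustering.** A U-net segments the muscle region
   inside the fascia lata (discarding subcutaneous fat, bone and marrow)
   from the T2/PD maps (or raw echoes). Inside that region, 16×16 two-channel
   patches are embedded by a convolutional auto-encoder trained with a
   combined reconstruction + triplet loss (DCAETL) under weak supervision
   from the fat-fraction labels, and k-means on the unit-hypersphere
   embedding separates viable muscle from IMAT. Intensity k-means,
   auto-encoder + k-means, and deep embedded clustering are included as
   comparison methods.

The biomarker is

```
IMAT fraction = Area_IMAT / Area_whole-muscle
```

per slice, banded into mild (0–33%), moderate (34–66%) and severe (67–100%)
disease.

Patient MESE data of this kind are not publicly deposited, so the package
ships a synthetic phantom generator (`make_phantom()`, `make_cohort()`) that
emulates an axial calf/thigh slice — SAT ring, fascia boundary, bones with
marrow, speckled IMAT infiltration at a controllable fraction, smooth
B1+/B1− field inhomogeneities, and Rician noise — with exact ground truth,
so the entire pipeline is testable end to end. The networks are implemented
natively in vectorized R (im2col convolutions over BLAS, hand-written
backpropagation, Adam).

## Worked example

```r
library(imatq)

protocol <- mese_protocol()                 # TR/TE 1479/8.7 ms, 17 echoes
dict <- build_dictionary(protocol)          # 146 T2 x 31 B1+ EPG curves

ph <- make_phantom(128, "calf", target_imat_fraction = 0.4, seed = 7)
series <- simulate_mese(ph, protocol, dict, snr = 50, seed = 7)

maps <- fit_two_component(series, dict, mask = ph$muscle_region_mask)
labels <- label_tissue_gt(maps$fat_fraction, ph$muscle_region_mask)
imat_fraction(labels)
#> [1] 0.3882429
severity_class(imat_fraction(labels))
#> [1] "moderate"
```

The phantom was asked for a 40% IMAT burden (achieved ground truth 40.0%);
dictionary mapping plus the two-compartment fat-fraction fit recover 38.8%
from the simulated noisy signal alone, which the banding rule classifies as
moderate disease.

The full two-stage pipeline (simulate a cohort → fit maps → train the U-net
→ train the DCAETL clusterer → biomarker) runs through one call:

```r
cfg <- pipeline_config(n_subjects = 12,
                       severity_mix = c(mild = 4, moderate = 4, severe = 4),
                       unet = unet_config(base_filters = 8, epochs = 8,
                                          augmentation_factor = 1, batch_size = 4),
                       dcae = dcae_config(epochs = 8), seed = 17)
res <- run_pipeline(cfg, dictionary = dict)
res$summary$biomarker$pearson_r   # agreement of predicted vs true fractions
```

A thin command-line front end over the same functions is installed at
`inst/cli/imatq.R` (`Rscript imatq.R run --n 12 --out results/`).

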