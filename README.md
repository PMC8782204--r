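# seegquake

Tools for the computational core of presurgical stereoelectroencephalography
(SEEG) evaluation in drug-resistant epilepsy:

* **Electrode contact localization** from a skull-stripped, co-registered
  post-implant CT volume: intensity thresholding → 3D Hough-transform line
  detection → Hough-initialized Gaussian-mixture clustering of the voxel
  cloud → center-of-mass contact segmentation with fixed-pitch stepping,
  plus the two geometric quality-control metrics used to validate it
  (axis–contact distance and adjacent-contact distance error).
* **Ictal analysis** — the Epileptogenicity Index (EI): channels are
  filtered to the high-gamma band (60–140 Hz), their squared, 500 ms
  smoothed, baseline-normalized energy (NHFE) is thresholded at
  `max(baseline) + 10·sd(baseline)` per channel, and each channel is scored
  `EI = TC × EC` where `TC` is the reciprocal of its onset rank and `EC`
  the mean NHFE in the 250 ms right after the earliest onset.
* **Interictal analysis** — the High-Frequency Events Index (HI): the
  80–250 Hz Hilbert envelope is thresholded at
  `2 × max(median_channel, median_global)`; supra-threshold runs closer
  than 20 ms are merged, runs shorter than 50 ms discarded, and HI is the
  per-channel event count.
* **Synthetic data with ground truth** (CT-like volumes with planted
  electrodes; recordings with planted seizure-onset ramps or ripple
  bursts) and **evaluation** (ROC/AUC of an index against clinician SOZ
  labels, one-to-one contact matching).

Who it is for: researchers and engineers working on SEEG localization and
seizure-onset-zone ranking who need a self-contained, testable
implementation — every stage can be exercised on generated data with known
truth, no patient data required.

## Worked example

```r
library(seegquake)

## --- localization on a synthetic CT with known truth -------------------
sv  <- synth_volume(electrode_spec(n_electrodes = 4), seed = 7)
loc <- locate_electrodes(sv$volume)
loc
#> <seeg_localization> 4 electrodes, 44 contacts
#> <seeg_geometry_qc> 44 contacts, 40 adjacent pairs
#>   axis-contact distance: median 0.0262 mm, max 0.067 mm
#>   adjacent distance: mean 3.492 mm (error sd 0.046)
match_contacts(loc$contact_sets, sv$truth)
#> <seeg_recovery> matched 44/44 truth contacts (44 found); error mean 0.0443 mm, max 0.139 mm
```

All four planted electrodes are found with their full contact counts. The
QC lines say the recovered contacts sit a median 0.026 mm from their
electrode's regressed axis (straightness) and consecutive contacts are
3.492 mm apart on average against the manufactured 3.5 mm pitch
(calibration); matching against the generator's truth confirms a mean
localization error of 0.044 mm on this noise level.

```r
## --- Epileptogenicity Index on a synthetic seizure ---------------------
g   <- synth_ictal_recording(n_channels = 6, duration_s = 24,
                             soz_channels = c(2, 4, 5), onset_time_s = 12,
                             onset_lags_s = c(0, 0.5, 1), snr = 5, seed = 1)
seg <- segment_spec(baseline = c(0, 10000), target = c(11000, 24000),
                    g$recording)
ei  <- epileptogenicity_index(g$recording, seg)
ei
#> Epileptogenicity Index (sorted by EI):
#>  channel threshold onset_s rank     TC     EC     EI
#>      ch2     2.966   12.35    1 1.0000 4.8085 4.8085
#>      ch4     2.910   12.82    2 0.5000 0.8882 0.4441
#>      ch5     3.373   13.41    3 0.3333 1.0472 0.3491
#>      ch1     3.475      NA   NA 0.0000 0.9375 0.0000
#>      ...
roc_auc(ei$EI, g$recording$channel_names %in% g$truth$soz_channels)$auc
#> [1] 1
```

The three channels with planted onsets (lags 0, 0.5, 1 s) are ranked
first, second, third; their time coefficients are exactly 1, 1/2, 1/3, and
the detected onset times track the planted stagger. Scoring EI against the
planted SOZ labels gives AUC 1 on this easy, high-SNR case.

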