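# Reference measurement tables

Published benchmark measurements from a 1000-slice lower-limb CT angiography
compression study, used as regression fixtures for the metric conventions:

- `cta_reference_quality.csv` — per-slice PSNR (dB) and MSE for three
  codecs: the variable-bit-rate ROI method (`mvar`), its fixed-rate variant
  (`mfix`), and whole-frame lossy JPEG2000 (`jp2k`). PSNR values of 78 dB
  pair with the sentinel MSE 0.001 (effectively lossless slices). The pairs
  establish the reference-peak convention MAX = 255 used by
  `psnr_from_mse()`.
- `cta_reference_sizes.csv` — average per-slice sizes (kB, 1024 bytes) and
  the printed compression-ratio labels for an uncompressed 512x512 16-bit
  slice (512 kB), three lossless codecs, and the variable-bit-rate ROI
  method; fixtures for `compression_ratio()` / `percent_reduction()`
  formatting.
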