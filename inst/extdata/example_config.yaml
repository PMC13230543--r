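# Example analysis configuration. Every setting is optional; omitted
# values fall back to the package defaults shown here.
landmark:
  likelihood_threshold: 0.70   # per-point adequacy criterion
  max_low_fraction: 0.50       # video excluded above this inadequate share
  adequacy_method: all         # or "mean"
  fps: 30
enhancement:
  clip_limit: 2.0
  tile_grid: [8, 8]
  gaussian_kernel: 5
  median_kernel: 3
  sharpen_amount: 1.0
  blue_hue: [200, 260]         # dye hue band, degrees
  min_saturation: 0.25
  min_value: 0.15
  blue_gain: 1.4
  blue_value_gain: 1.4
  threshold: otsu
  mask_combine: both           # threshold mask intersected with blue band
geometry:
  v_glottis: 1.0               # scale on the glottic square diagonal
  v_pyriform: 1.0              # scale on the pyriform rectangle height
  magnification: 3
classification:
  cell_presence_threshold: 0.01
  severe_includes_50: false
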