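# Masson's trichrome stain-class windows in HSL space.
# Hue in degrees (lo > hi wraps through 0); saturation/lightness in [0,1].
collagen:
  hue: [150, 250]
  saturation: [0.1, 1.0]
  lightness: [0.1, 0.93]
cytoplasm:
  hue: [250, 25]
  saturation: [0.1, 1.0]
  lightness: [0.1, 0.93]
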