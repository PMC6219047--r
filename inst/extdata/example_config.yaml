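# Pipeline configuration for the default synthetic scene geometry.
# ROIs are 1-based inclusive pixel bounds of the fixed camera frame.
tip_roi:
  top: 45
  bottom: 315
  left: 5
  right: 315
holder_roi:
  top: 10
  bottom: 49
  left: 5
  right: 315
threshold: 40          # pure-red binarisation threshold (0-255)
red_sign: r_minus_y    # colour-difference convention
holder_luminance_threshold: 140
bound_mode: relative   # pump-check bound: relative (%) or absolute (steps)
bound_value: 5
# calibration: calibration.json   # path resolved relative to this file
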