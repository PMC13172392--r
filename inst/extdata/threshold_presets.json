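{
  "uniform": {
    "channel_mode": "luminance_inverted",
    "blur_radius_px": 1,
    "close_radius_px": 2,
    "open_radius_px": 2,
    "min_object_area_px": 120,
    "max_hole_area_px": 200
  },
  "saturation": {
    "channel_mode": "saturation",
    "blur_radius_px": 1,
    "close_radius_px": 2,
    "open_radius_px": 2,
    "min_object_area_px": 120,
    "max_hole_area_px": 200
  },
  "aggressive_cleanup": {
    "channel_mode": "luminance_inverted",
    "blur_radius_px": 2,
    "close_radius_px": 3,
    "open_radius_px": 3,
    "min_object_area_px": 300,
    "max_hole_area_px": 500
  }
}
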