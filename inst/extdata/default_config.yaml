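# Default pipeline configuration: every numerical choice of the tracing and
# snGFR stages in one auditable place. Load with load_config(); absent
# fields inherit these defaults.
trace:
  snap_radius_um: 5        # ridge-snapping search radius
  spacing_um: 1            # centerline resampling step
  profile_step_um: 0.25    # perpendicular profile sampling for FWHM radius
  max_radius_um: 20        # largest radius the profile search considers
  n_fill_frames: 3         # MIP over this many final (filled) frames
  smooth_window: 7         # centerline smoothing window, points
sngfr:
  position_spacing_um: 2   # arc spacing of intensity measurement positions
  n_baseline_frames: 5     # pre-bolus frames for baseline subtraction
  plateau_frames: 10       # final frames whose median is the plateau
  noise_floor_sd: 3        # plateau must exceed this x baseline SD
  min_valid_fraction: 0.6  # required fraction of positions with arrivals
min_tubule_length_um: 45   # inclusion criterion for proximal tubules
max_nephrons_per_animal: 3 # batch cap (warning when exceeded)
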