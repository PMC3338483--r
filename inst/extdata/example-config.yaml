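# Example run configuration for geledge.
# Units: um (lengths), Pa (moduli), um/hr (speeds), um^2 (areas), minutes
# (frame interval), hours (duration).
seed: 1
heights: [12.5, 25, 50, 100, 200]
n_tracks: 45            # total tracked cells per condition (3 fields x 15)
n_cells_morpho: 36
drift_scale: 1.5        # gel swelling drift, um per frame
material:
  youngs_modulus: 450   # Matrigel
  poisson_ratio: 0.45
indenter:
  radius: 5             # 10 um diameter sphere, cell-sized
  max_depth: 5
  n_steps: 10
conditions:
  matrigel40_low:       # lowest observation plane, 40% v/v gel
    area_mean: 1340
    area_sd: 470
    ar_mean: 10.4
    ar_sd: 7.3
    speed_mean: 29.5
    speed_sd: 11.3
    spindle_fraction: 0.9
  matrigel40_high:      # highest observation plane (bulk)
    area_mean: 400
    area_sd: 270
    ar_mean: 1.6
    ar_sd: 0.8
    speed_mean: 7.6
    speed_sd: 3.1
    spindle_fraction: 0
  glass:                # bare glass control
    area_mean: 2309
    area_sd: 1232
    ar_mean: 2.2
    ar_sd: 1.5
    speed_mean: 28.2
    speed_sd: 9.7
    spindle_fraction: 0
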