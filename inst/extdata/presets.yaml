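# Calibrated generator presets for the wildtype (wt) and conditional-knockout
# (cko) phenotypes. Generative parameters were calibrated once, by simulation,
# so that the analysis pipeline's outputs land on the group statistics the
# presets emulate. Units are stated per key.
version: 1
spikes:
  wt:
    label: wt
    duration_s: 100
    bursts_per_100s_values: [3, 4, 5]
    bursts_per_100s_probs: [0.2, 0.6, 0.2]
    minibursts_meanlog: 2.59          # log-scale median of minibursts per burst
    minibursts_sdlog: 0.28
    minibursts_min: 8
    minibursts_max: 30
    spikes_per_miniburst_mean: [2.54, 3.75]  # per-burst mean, uniform range
    miniburst_interval_s: [0.104, 0.161]    # per-burst mean interval, uniform range
    miniburst_interval_jitter_s: 0.012
    onset_spikes: 5                   # high-frequency onset volley of each burst
    onset_first_isi_s: [0.0006, 0.0010]
    intra_isi_mean_s: 0.004
    intra_isi_range_s: [0.0015, 0.015]
    background_rate_hz: 6.25
    suppression_per_spike_s: 0.128    # post-burst suppressed period, scales with size
    suppression_min_s: 2.0
    unit_jitter_sdlog: 0.05
  cko:
    label: cko
    duration_s: 100
    bursts_per_100s_values: [1]
    bursts_per_100s_probs: [1.0]
    minibursts_meanlog: 2.08
    minibursts_sdlog: 0.30
    minibursts_min: 6
    minibursts_max: 12
    spikes_per_miniburst_mean: [2.2, 3.2]
    miniburst_interval_s: [0.075, 0.115]
    miniburst_interval_jitter_s: 0.012
    onset_spikes: 5
    onset_first_isi_s: [0.0006, 0.0010]
    intra_isi_mean_s: 0.004
    intra_isi_range_s: [0.0015, 0.015]
    background_rate_hz: 5.6
    suppression_per_spike_s: 0.235
    suppression_min_s: 3.0
    unit_jitter_sdlog: 0.06
imaging:
  wt_ca:
    label: wt
    modality: fura_ratio
    field_px: [72, 112]               # rows, cols
    pixel_size_um: 2
    n_frames: 400
    frame_interval_s: 1
    baseline_level: 2000              # 16-bit camera counts per channel
    noise_sd: 20
    event_rate_hz: 0.0285
    min_onset_gap_frames: 20
    event_area_mean_um2: 3920
    event_area_sdlog: 0.40
    event_aspect: 2.5
    event_amplitude: 0.40             # fraction of baseline
    growth_profile: [0.35, 0.70, 1.0, 1.0, 0.65, 0.30]
    speed_um_per_frame: 8             # wave propagation along the tonotopic (x) axis
    band_rows_um: [20, 124]           # strip standing for Koelliker's organ
  cko_ca:
    label: cko
    modality: fura_ratio
    field_px: [72, 112]
    pixel_size_um: 2
    n_frames: 400
    frame_interval_s: 1
    baseline_level: 2000
    noise_sd: 20
    event_rate_hz: 0.0123
    min_onset_gap_frames: 8
    event_area_mean_um2: 656
    event_area_sdlog: 0.35
    event_aspect: 1.6
    event_amplitude: 0.30
    growth_profile: [0.6, 1.0, 1.0, 0.5]
    speed_um_per_frame: 0
    band_rows_um: [20, 124]
  wt_dic:
    label: wt
    modality: dic
    field_px: [72, 112]
    pixel_size_um: 2
    n_frames: 1200
    frame_interval_s: 1
    baseline_level: 1000
    noise_sd: 12
    event_rate_hz: 0.0171
    min_onset_gap_frames: 20
    event_area_mean_um2: 7700
    event_area_sdlog: 0.35
    event_aspect: 2.5
    event_amplitude: 0.35
    growth_profile: [0.35, 0.70, 1.0, 1.0, 0.65, 0.30]
    speed_um_per_frame: 8
    band_rows_um: [20, 124]
  cko_dic:
    label: cko
    modality: dic
    field_px: [72, 112]
    pixel_size_um: 2
    n_frames: 1200
    frame_interval_s: 1
    baseline_level: 1000
    noise_sd: 12
    event_rate_hz: 0.0003
    min_onset_gap_frames: 10
    event_area_mean_um2: 40
    event_area_sdlog: 0.30
    event_aspect: 1.3
    event_amplitude: 0.30
    growth_profile: [1.0, 1.0]
    speed_um_per_frame: 0
    band_rows_um: [20, 124]
fra:
  wt:
    label: wt
    cf_range_khz: [5.3, 30.5]
    threshold_db: 0.6
    q10: 5.5                          # median sharpness target; slopes derived per unit
    q_jitter_sdlog: 0.25
    max_rate_hz: 263.6
    spont_rate_hz: 5
    sat_range_db: 20
    slope_asymmetry: 1.3              # low side shallower than high side
    freqs_khz: {from: 3.0, to: 54.0, per_octave: 12}
    levels_db: {from: -10, to: 80, by: 5}
    reps: 5
    window_s: 0.05
  cko:
    label: cko
    cf_range_khz: [5.3, 30.5]
    threshold_db: 6.3
    q10: 4.7
    q_jitter_sdlog: 0.30
    max_rate_hz: 223.9
    spont_rate_hz: 5
    sat_range_db: 20
    slope_asymmetry: 1.3
    freqs_khz: {from: 3.0, to: 54.0, per_octave: 12}
    levels_db: {from: -10, to: 80, by: 5}
    reps: 5
    window_s: 0.05
maps:
  wt:
    label: wt
    polygon_semiaxes_um: [175, 115]   # mediolateral x dorsoventral
    polygon_vertices: 24
    polygon_scale_jitter_sd: 0.05
    grid_spacing_um: 20
    grid_margin_um: 20
    area_frac_target: 0.10            # responsive (>2 mV) fraction of MNTB area
    width_frac_target: 0.27           # >10 mV mediolateral extent / MNTB length
    amp_max_mv: 26
    ap_radius_um: 15
    noise_sd_mv: 0.4
    center_jitter_um: 20
  cko:
    label: cko
    polygon_semiaxes_um: [165, 106]
    polygon_vertices: 24
    polygon_scale_jitter_sd: 0.05
    grid_spacing_um: 20
    grid_margin_um: 20
    area_frac_target: 0.20
    width_frac_target: 0.454
    amp_max_mv: 26
    ap_radius_um: 15
    noise_sd_mv: 0.4
    center_jitter_um: 20
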