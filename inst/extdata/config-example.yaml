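# Example pcgseg configuration: every value shown is the method default.
filter:
  ecg_hp_cutoff: 10      # Hz
  ecg_lp_cutoff: 35      # Hz
  ecg_fir_order: 250     # taps per stage = order + 1
  pcg_low: 20            # Hz
  pcg_high: 100          # Hz
  pcg_order: 5
  pcg_ripple_db: 0.5

segmentation:
  amp_frac: 0.05         # amplitude threshold, fraction of envelope max
  join_frac: 0.10        # join gap, fraction of mean RR
  fp_frac: 0.20          # pair pruning, fraction of mean RR
  fp_frac2: 0.40         # triple pruning, fraction of mean RR
  s1_pre_ms: 50          # S1 window before the R-peak, ms
  s1_rr_frac: 0.18       # S1/S2 boundary, fraction of beat RR
  se_window_n: 20        # Shannon-energy window, samples
  norm_window_s: 1       # normalization window, s
  prominence_frac: 0.02  # minimum component-lobe prominence

simulate:
  duration_s: 60
  heart_rate: 66
  noise_std: 0.05
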