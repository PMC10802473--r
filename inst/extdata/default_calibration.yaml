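# Versioned default calibration for hsrkit.
# parameters: wild-type circuit parameters (a.u., minutes).
# synthetic: ground-truth constants used by the seeded data generators.
version: 1
parameters:
  k_U0: 0.01        # basal client production (a.u./min)
  s_heat: 1500.0     # client production fold-increase, heat
  s_eth: 1200.0      # client production fold-increase, ethanol
  k_bU: 0.5        # Hsp70-client association (1/(a.u. min))
  k_rel: 5.0       # productive client release (1/min) -- auxiliary feedback
  k_offU: 0.5     # non-productive client release (1/min)
  k_bF0: 0.0777      # max Hsp70-Hsf1 association (1/(a.u. min))
  k_uF: 0.2        # Hsp70-Hsf1 dissociation (1/min)
  K_sis: 0.2     # client level at half-maximal affinity switch (a.u.)
  h_sis: 4.0       # affinity-switch Hill coefficient
  beta0: 0.02      # basal Hsp70 synthesis (a.u./min)
  beta1: 2.5      # max Hsf1-dependent Hsp70 synthesis (a.u./min)
  K_hsf: 0.0593      # Hill constant, Hsf1-driven Hsp70 synthesis (a.u.)
  n_hsf: 6.0
  alpha_y: 1.0     # max reporter transcription (a.u./min)
  K_y: 0.5         # Hill constant, reporter promoter (a.u.)
  n_y: 2.0
  m_mat: 0.05      # YFP maturation (1/min)
  gamma: 0.004     # dilution/degradation (1/min)
  F_tot: 1.0       # total Hsf1 (a.u., conserved)
synthetic:
  ec50_true: 6.9       # % v/v ethanol, half-maximal reporter activation
  ic50_true: 6.6       # % v/v ethanol, half-maximal growth inhibition
  hill_n_yfp: 6.0
  hill_n_growth: 8.0
  yfp_floor: 1.0       # 4-h reporter fold change without ethanol
  yfp_ceiling: 5.0     # saturating 4-h reporter fold change
  growth_floor: 0.05   # relative growth at saturating ethanol
  n_genes: 42
  basal_min: 10.0      # lowest basal reporter level (a.u.)
  basal_decades: 3.3   # log10 span of basal levels
  fold_range: [1.05, 10.0]
  t50_range: [20.0, 150.0]  # min
  kinetic_rho: -0.75   # copula correlation, fold change vs t50
  replicate_cv: 0.05
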