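# Default simulation parameters for synthetic SNaPshot cohorts.
#
# Per-locus linear age model of the true methylation fraction:
#   level = clamp01(b0 + b1 * age + Normal(0, sigma^2))
# b0: fraction at age 0; b1: fraction per year; sigma: biological spread.
# Slopes and spreads are calibrated so that, for 60 samples with ages
# uniform on 23..70 years, the realized |Pearson r| of level vs age per
# locus sits in the moderate band (about 0.28-0.60) typical of
# single-locus buccal-swab markers. C1orf132 methylation declines with
# age, hence its negative slope.
n_samples: 60
age_min: 23
age_max: 70
loci:
  ELOVL2:   {b0: 0.35, b1:  0.004, sigma: 0.094}
  FHL2:     {b0: 0.25, b1:  0.002, sigma: 0.095}
  KLF14:    {b0: 0.10, b1:  0.004, sigma: 0.075}
  C1orf132: {b0: 0.80, b1: -0.004, sigma: 0.118}
  TRIM59:   {b0: 0.20, b1:  0.004, sigma: 0.113}
# replicate structure: 2 bisulfite conversions x 2 amplifications
n_conversions: 2
n_amplifications: 2
replicate_noise_sd: 0.01      # fraction, technical spread per replicate
conversion_shift: 0.0         # fraction, batch effect between conversions
total_intensity_mean: 4000    # RFU, mean summed peak intensity per locus
total_intensity_sd: 1200      # RFU
intensity_noise_cv: 0.05      # multiplicative channel noise
saturation_rfu: 32000         # instrument ceiling
control_meth_level: 0.98      # fully methylated control DNA
control_unmeth_level: 0.02    # fully unmethylated control DNA
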