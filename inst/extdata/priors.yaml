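# Uniform prior bounds for the demographic parameters.
# Times are in generations before present (25 years per generation).
# STR_MUTRATE, KNeo and T_STARTEXP bounds are fixed by the study design;
# the remaining bounds are reconstructed: smallest round intervals
# containing the published 95% posterior intervals.
priors:
  T_STARTEXP: [3200, 6000]        # start of the expansion in Africa
  T_OOA: [1200, 3000]             # out-of-sub-Saharan-Africa time
  Ne_ANC: [5000, 20000]           # ancestral diploid size          (reconstructed)
  K: [50, 2000]                   # diploid carrying capacity       (reconstructed)
  r: [0.2, 1.0]                   # logistic growth rate            (reconstructed)
  m: [0.05, 0.3]                  # migration rate per gene         (reconstructed)
  LDD_PROP: [0.0, 0.05]           # LDD share of the migrant pool   (reconstructed)
  mu_bar: [2.0, 6.0]              # mean LDD distance, demes        (reconstructed)
  alpha: [0.5, 2.0]               # gamma shape of the LDD kernel   (reconstructed)
  STR_MUTRATE: [5.0e-5, 3.0e-4]   # per-locus per-generation mutation rate
  KNeo: [2500, 7500]              # post-Neolithic carrying capacity
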