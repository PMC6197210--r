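# Default experiment configuration for the immunodem pipeline.
# Any block or key may be omitted; package defaults then apply.
seed: 1
outdir: immunodem-output
plots: false
stages: [tradeoff, demography, scenarios, maternal]

tradeoff:
  gamma: 4
  eta: 0.8
  rho: 0.01
  mu_b: 0.0166667      # 1/60 per year
  mu_d: 1
  i_x: 0.5             # focal-age infection probability for the landscape
  se_axis_n: 200
  mud_max: 5
  map_i_x: 0.15        # incidence for the discrimination-response map

demography:
  n_ages: 60
  maturity: 15
  i_x: 0.15
  mu_b: 0.0166667
  fertility: 1.272     # calibrated so the baseline growth rate is ~1

scenarios:
  boost_factor: 2
  penalty_c: 0.5

maternal:
  nonself_mean: 2      # unit-scale trait distributions separated by 2
  i_x: 0.15
  mu_d: 1.5
  mu_i: 0.45
  mu_id: 0.5
  offspring_infection: 0.8
  memory_discount: 1
  transfer_efficacy: 0.9
  offspring_immunopathology: 0
  n_replicates: 20000
  n_blocks: 10
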