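# Example synthetic-cohort configuration (mirrors generator_config()).
# The defaults emulate a 1301-participant, 85-centre critical-care trial;
# this scaled-down example keeps the same shape at a tenth of the size.
n_per_arm: [65, 66]
n_sites: 9
largest_site_size: 30
site_size_decay: 0.97
alpha_true: -0.745
beta_true: 0.103
site_sd: 0.3
gamma_creatinine: 0.5
gamma_sofa: 0.07
gamma_bmi: 0.0
delta_creatinine: 0.0
delta_sofa: 0.0
delta_bmi: 0.0
discharge_hazard: {high: 0.0273, usual: 0.030}
death_hazard: {high: 0.008, usual: 0.008}
n_missing_outcome: 1
n_missing_creatinine: 9
seed: 2026
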