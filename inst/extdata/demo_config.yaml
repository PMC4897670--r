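seed: 20160101
simulation:
  n_individuals: 599
analysis:
  covariates:
  - age
  - sex
  - bmi
  - smoking
  - med_htn
  - med_dm
  - med_lipid
  outcomes:
  - log_crp
  - log_saa
  triallelic: rs3091244
  bonferroni:
    CRP: 5
    SAA1: 4
  haplotype_floor: 0.01
quartile:
  mediator: saa
  exposure: dom_rs4638289
  outcome: log_crp
mediation:
  level: 0.05
  pairs:
  - iv: add_rs4638289
    mediator: log_saa
    dv: log_crp
  - iv: add_rs7131332
    mediator: log_saa
    dv: log_crp
  - iv: add_rs11024591
    mediator: log_saa
    dv: log_crp
  - iv: hap_SAA1_AAAC
    mediator: log_saa
    dv: log_crp
  - iv: hap_CRP_AAGCG
    mediator: log_crp
    dv: log_saa
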