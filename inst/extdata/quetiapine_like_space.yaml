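token_sets:
- name: compartments
  options:
  - label: 1cpt
    n_effects: 0
    n_extra_params: 0
    payload:
      compartments: 1
  - label: 2cpt
    n_effects: 2
    n_extra_params: 2
    payload:
      compartments: 2
  - label: 3cpt
    n_effects: 4
    n_extra_params: 4
    payload:
      compartments: 3
- name: age_cl
  options:
  - label: none
    n_effects: 0
    n_extra_params: 0
  - label: power
    n_effects: 1
    n_extra_params: 1
    payload:
      covariate:
        parameter: CL
        covariate: AGE
        form: power
- name: wt_cl
  options:
  - label: none
    n_effects: 0
    n_extra_params: 0
  - label: power
    n_effects: 1
    n_extra_params: 1
    payload:
      covariate:
        parameter: CL
        covariate: WT
        form: power
- name: wt_v
  options:
  - label: none
    n_effects: 0
    n_extra_params: 0
  - label: power
    n_effects: 1
    n_extra_params: 1
    payload:
      covariate:
        parameter: V
        covariate: WT
        form: power
- name: sex_cl
  options:
  - label: none
    n_effects: 0
    n_extra_params: 0
  - label: proportional_shift
    n_effects: 1
    n_extra_params: 1
    payload:
      covariate:
        parameter: CL
        covariate: SEX
        form: proportional_shift
- name: smok_cl
  options:
  - label: none
    n_effects: 0
    n_extra_params: 0
  - label: proportional_shift
    n_effects: 1
    n_extra_params: 1
    payload:
      covariate:
        parameter: CL
        covariate: SMOK
        form: proportional_shift
- name: bsv_V
  options:
  - label: none
    n_effects: 0
    n_extra_params: 0
  - label: BSV V
    n_effects: 1
    n_extra_params: 1
    payload:
      bsv: V
- name: bsv_Q2
  options:
  - label: none
    n_effects: 0
    n_extra_params: 0
  - label: BSV Q2
    n_effects: 1
    n_extra_params: 1
    payload:
      bsv: Q2
- name: bsv_V2
  options:
  - label: none
    n_effects: 0
    n_extra_params: 0
  - label: BSV V2
    n_effects: 1
    n_extra_params: 1
    payload:
      bsv: V2
- name: ruv
  options:
  - label: proportional
    n_effects: 0
    n_extra_params: 1
    payload:
      ruv: proportional
  - label: additive
    n_effects: 0
    n_extra_params: 1
    payload:
      ruv: additive
  - label: combined
    n_effects: 1
    n_extra_params: 2
    payload:
      ruv: combined
- name: absorption
  options:
  - label: first_order
    n_effects: 0
    n_extra_params: 0
  - label: first_order_lag
    n_effects: 1
    n_extra_params: 1
    payload:
      lag: yes
effect_limit: 6
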