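format: angiosprout-model
version: 1
species:
- notch1_mRNA
- notch1
- dll4_mRNA
- dll4
- nicd
- cis_complex
- trans_complex
- vegfr1_mRNA
- svegfr1_mRNA
- mvegfr1
- mvegfr1_bound
- svegfr1_internal
- vegfr2_mRNA
- vegfr2
- vegfr2_bound
- vegfr2_active
- vegf_ext
- svegfr1_ext
- svegfr1b_ext
- dll4_nb
- filopodia
env_species:
- vegf_ext
- svegfr1_ext
- svegfr1b_ext
- dll4_nb
rule_species:
- filopodia
parameters:
  vmax_tc_notch1: 16.0
  a_notch1_nicd: 4.0
  m0_notch1_nicd: 250.0
  a_notch1_auto: 2.0
  m0_notch1_auto: 1500.0
  vmax_tc_dll4: 60.0
  a_dll4_vegfr2: 100.0
  m0_dll4_vegfr2: 350.0
  vmax_tc_vegfr1: 44.0
  a_vegfr1_nicd: 12.0
  m0_vegfr1_nicd: 250.0
  vmax_tc_svegfr1: 44.0
  a_svegfr1_nicd: 12.0
  m0_svegfr1_nicd: 250.0
  vmax_tc_vegfr2: 40.0
  a_vegfr2_nicd: 30.0
  m0_vegfr2_nicd: 250.0
  hill_h: 2.0
  k_tl_notch1: 12.0
  k_tl_dll4: 2.4
  k_tl_mvegfr1: 20.0
  k_tl_svegfr1: 20.0
  k_tl_vegfr2: 2.0
  kc: 4.0e-05
  kt: 0.0004
  k_nicd_release: 2.0
  k_on_mvegfr1: 0.0001
  k_off_mvegfr1: 0.05
  k_on_svegfr1: 0.0002
  k_off_svegfr1: 0.05
  k_on_vegfr2: 2.0e-06
  k_off_vegfr2: 0.5
  k_act_decay: 1.0
  k_export_svegfr1: 0.5
  k_deg_notch1_mrna: 0.2
  k_deg_dll4_mrna: 0.2
  k_deg_vegfr1_mrna: 0.2
  k_deg_vegfr2_mrna: 0.2
  k_deg_notch1: 0.1
  k_deg_dll4: 0.15
  k_nicd_degradation: 0.35
  k_deg_cis: 0.2
  k_deg_receptor: 0.12
initial:
  notch1_mRNA: 40.0
  notch1: 2000.0
  dll4_mRNA: 60.0
  dll4: 2000.0
  nicd: 300.0
  cis_complex: 500.0
  trans_complex: 50.0
  vegfr1_mRNA: 100.0
  svegfr1_mRNA: 100.0
  mvegfr1: 4000.0
  mvegfr1_bound: 0.0
  svegfr1_internal: 500.0
  vegfr2_mRNA: 60.0
  vegfr2: 1000.0
  vegfr2_bound: 0.0
  vegfr2_active: 0.0
  filopodia: 0.0
reactions:
- name: tc_notch1
  law: hill_activation
  params:
    vmax: vmax_tc_notch1
    a: a_notch1_nicd
    m0: m0_notch1_nicd
    h: hill_h
    a2: a_notch1_auto
    m02: m0_notch1_auto
  modifiers:
    mod:
    - nicd
    mod2:
    - notch1
  stoich:
    notch1_mRNA: 1.0
- name: tc_dll4
  law: hill_activation
  params:
    vmax: vmax_tc_dll4
    a: a_dll4_vegfr2
    m0: m0_dll4_vegfr2
    h: hill_h
  modifiers:
    mod:
    - vegfr2_bound
    - vegfr2_active
  stoich:
    dll4_mRNA: 1.0
- name: tc_vegfr1
  law: hill_activation
  params:
    vmax: vmax_tc_vegfr1
    a: a_vegfr1_nicd
    m0: m0_vegfr1_nicd
    h: hill_h
  modifiers:
    mod:
    - nicd
  stoich:
    vegfr1_mRNA: 1.0
- name: tc_svegfr1
  law: hill_activation
  params:
    vmax: vmax_tc_svegfr1
    a: a_svegfr1_nicd
    m0: m0_svegfr1_nicd
    h: hill_h
  modifiers:
    mod:
    - nicd
  stoich:
    svegfr1_mRNA: 1.0
- name: tc_vegfr2
  law: hill_repression
  params:
    vmax: vmax_tc_vegfr2
    a: a_vegfr2_nicd
    m0: m0_vegfr2_nicd
    h: hill_h
  modifiers:
    mod:
    - nicd
  stoich:
    vegfr2_mRNA: 1.0
- name: tl_notch1
  law: mass_action
  params:
    k: k_tl_notch1
  rate_species:
  - notch1_mRNA
  stoich:
    notch1: 1.0
- name: tl_dll4
  law: mass_action
  params:
    k: k_tl_dll4
  rate_species:
  - dll4_mRNA
  stoich:
    dll4: 1.0
- name: tl_mvegfr1
  law: mass_action
  params:
    k: k_tl_mvegfr1
  rate_species:
  - vegfr1_mRNA
  stoich:
    mvegfr1: 1.0
- name: tl_svegfr1
  law: mass_action
  params:
    k: k_tl_svegfr1
  rate_species:
  - svegfr1_mRNA
  stoich:
    svegfr1_internal: 1.0
- name: tl_vegfr2
  law: mass_action
  params:
    k: k_tl_vegfr2
  rate_species:
  - vegfr2_mRNA
  stoich:
    vegfr2: 1.0
- name: trans_bind
  law: mass_action
  params:
    k: kt
  rate_species:
  - notch1
  - dll4_nb
  stoich:
    notch1: -1.0
    dll4_nb: -1.0
    trans_complex: 1.0
- name: nicd_release
  law: mass_action
  params:
    k: k_nicd_release
  rate_species:
  - trans_complex
  stoich:
    trans_complex: -1.0
    nicd: 1.0
- name: cis_bind
  law: mass_action
  params:
    k: kc
  rate_species:
  - notch1
  - dll4
  stoich:
    notch1: -1.0
    dll4: -1.0
    cis_complex: 1.0
- name: mvegfr1_bind
  law: mass_action
  params:
    k: k_on_mvegfr1
  rate_species:
  - mvegfr1
  - vegf_ext
  stoich:
    mvegfr1: -1.0
    vegf_ext: -1.0
    mvegfr1_bound: 1.0
- name: mvegfr1_unbind
  law: mass_action
  params:
    k: k_off_mvegfr1
  rate_species:
  - mvegfr1_bound
  stoich:
    mvegfr1_bound: -1.0
    mvegfr1: 1.0
    vegf_ext: 1.0
- name: vegfr2_bind
  law: mass_action
  params:
    k: k_on_vegfr2
  rate_species:
  - vegfr2
  - vegf_ext
  stoich:
    vegfr2: -1.0
    vegf_ext: -1.0
    vegfr2_bound: 1.0
- name: vegfr2_unbind_activate
  law: mass_action
  params:
    k: k_off_vegfr2
  rate_species:
  - vegfr2_bound
  stoich:
    vegfr2_bound: -1.0
    vegfr2_active: 1.0
    vegf_ext: 1.0
- name: vegfr2_active_decay
  law: mass_action
  params:
    k: k_act_decay
  rate_species:
  - vegfr2_active
  stoich:
    vegfr2_active: -1.0
    vegfr2: 1.0
- name: svegfr1_export
  law: mass_action
  params:
    k: k_export_svegfr1
  rate_species:
  - svegfr1_internal
  stoich:
    svegfr1_internal: -1.0
    svegfr1_ext: 1.0
- name: deg_notch1_mRNA
  law: mass_action
  params:
    k: k_deg_notch1_mrna
  rate_species:
  - notch1_mRNA
  stoich:
    notch1_mRNA: -1.0
- name: deg_dll4_mRNA
  law: mass_action
  params:
    k: k_deg_dll4_mrna
  rate_species:
  - dll4_mRNA
  stoich:
    dll4_mRNA: -1.0
- name: deg_vegfr1_mRNA
  law: mass_action
  params:
    k: k_deg_vegfr1_mrna
  rate_species:
  - vegfr1_mRNA
  stoich:
    vegfr1_mRNA: -1.0
- name: deg_svegfr1_mRNA
  law: mass_action
  params:
    k: k_deg_vegfr1_mrna
  rate_species:
  - svegfr1_mRNA
  stoich:
    svegfr1_mRNA: -1.0
- name: deg_vegfr2_mRNA
  law: mass_action
  params:
    k: k_deg_vegfr2_mrna
  rate_species:
  - vegfr2_mRNA
  stoich:
    vegfr2_mRNA: -1.0
- name: deg_notch1
  law: mass_action
  params:
    k: k_deg_notch1
  rate_species:
  - notch1
  stoich:
    notch1: -1.0
- name: deg_dll4
  law: mass_action
  params:
    k: k_deg_dll4
  rate_species:
  - dll4
  stoich:
    dll4: -1.0
- name: deg_nicd
  law: mass_action
  params:
    k: k_nicd_degradation
  rate_species:
  - nicd
  stoich:
    nicd: -1.0
- name: deg_cis_complex
  law: mass_action
  params:
    k: k_deg_cis
  rate_species:
  - cis_complex
  stoich:
    cis_complex: -1.0
- name: deg_mvegfr1
  law: mass_action
  params:
    k: k_deg_receptor
  rate_species:
  - mvegfr1
  stoich:
    mvegfr1: -1.0
- name: deg_mvegfr1_bound
  law: mass_action
  params:
    k: k_deg_receptor
  rate_species:
  - mvegfr1_bound
  stoich:
    mvegfr1_bound: -1.0
- name: deg_svegfr1_internal
  law: mass_action
  params:
    k: k_deg_receptor
  rate_species:
  - svegfr1_internal
  stoich:
    svegfr1_internal: -1.0
- name: deg_vegfr2
  law: mass_action
  params:
    k: k_deg_receptor
  rate_species:
  - vegfr2
  stoich:
    vegfr2: -1.0
- name: deg_vegfr2_bound
  law: mass_action
  params:
    k: k_deg_receptor
  rate_species:
  - vegfr2_bound
  stoich:
    vegfr2_bound: -1.0
- name: deg_vegfr2_active
  law: mass_action
  params:
    k: k_deg_receptor
  rate_species:
  - vegfr2_active
  stoich:
    vegfr2_active: -1.0
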