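- name: one_oa_code
  label: One OA code
  oa_rule: exactly_one
  min_separation_days: 7
- name: one_pain_code
  label: One knee pain code
  pain_rule: exactly_one
  min_separation_days: 7
- name: oa2_6mo
  label: '>=2 OA codes within 6 months'
  oa_rule:
    at_least: 2
  window_days: 183
  min_separation_days: 7
- name: pain2_6mo
  label: '>=2 knee pain codes within 6 months'
  pain_rule:
    at_least: 2
  window_days: 183
  min_separation_days: 7
- name: oa_pain_6mo
  label: '>=1 OA and >=1 knee pain code within 6 months'
  oa_rule:
    at_least: 1
  pain_rule:
    at_least: 1
  window_days: 183
  min_separation_days: 7
- name: oa2_12mo
  label: '>=2 OA codes within 12 months'
  oa_rule:
    at_least: 2
  window_days: 365
  min_separation_days: 7
- name: pain2_12mo
  label: '>=2 knee pain codes within 12 months'
  pain_rule:
    at_least: 2
  window_days: 365
  min_separation_days: 7
- name: oa_pain_12mo
  label: '>=1 OA and >=1 knee pain code within 12 months'
  oa_rule:
    at_least: 1
  pain_rule:
    at_least: 1
  window_days: 365
  min_separation_days: 7
- name: one_oa_code_img
  label: One OA code + imaging within 2 years
  oa_rule: exactly_one
  min_separation_days: 7
  require_imaging_within_days: 730
- name: one_pain_code_img
  label: One knee pain code + imaging within 2 years
  pain_rule: exactly_one
  min_separation_days: 7
  require_imaging_within_days: 730
- name: oa2_6mo_img
  label: '>=2 OA codes within 6 months + imaging within 2 years'
  oa_rule:
    at_least: 2
  window_days: 183
  min_separation_days: 7
  require_imaging_within_days: 730
- name: pain2_6mo_img
  label: '>=2 knee pain codes within 6 months + imaging within 2 years'
  pain_rule:
    at_least: 2
  window_days: 183
  min_separation_days: 7
  require_imaging_within_days: 730
- name: oa_pain_6mo_img
  label: '>=1 OA and >=1 knee pain code within 6 months + imaging within 2 years'
  oa_rule:
    at_least: 1
  pain_rule:
    at_least: 1
  window_days: 183
  min_separation_days: 7
  require_imaging_within_days: 730
- name: oa2_12mo_img
  label: '>=2 OA codes within 12 months + imaging within 2 years'
  oa_rule:
    at_least: 2
  window_days: 365
  min_separation_days: 7
  require_imaging_within_days: 730
- name: pain2_12mo_img
  label: '>=2 knee pain codes within 12 months + imaging within 2 years'
  pain_rule:
    at_least: 2
  window_days: 365
  min_separation_days: 7
  require_imaging_within_days: 730
- name: oa_pain_12mo_img
  label: '>=1 OA and >=1 knee pain code within 12 months + imaging within 2 years'
  oa_rule:
    at_least: 1
  pain_rule:
    at_least: 1
  window_days: 365
  min_separation_days: 7
  require_imaging_within_days: 730
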