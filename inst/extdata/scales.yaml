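# Psychometric instrument definitions: instruments are data, not code.
# response_range is the on-file item coding; recode_offset is added to each
# item before a sum score is formed (e.g. 1-4 responses recoded to 0-3);
# dichotomize_at is a threshold on the recoded sum (sum >= threshold -> 1).
gad7:
  items: [gad7_1, gad7_2, gad7_3, gad7_4, gad7_5, gad7_6, gad7_7]
  response_range: [1, 4]
  scoring: sum
  recode_offset: -1
  dichotomize_at: 10
phq9:
  items: [phq9_1, phq9_2, phq9_3, phq9_4, phq9_5, phq9_6, phq9_7, phq9_8, phq9_9]
  response_range: [1, 4]
  scoring: sum
  recode_offset: -1
  dichotomize_at: 10
bat12:
  items: [bat12_1, bat12_2, bat12_3, bat12_4, bat12_5, bat12_6,
          bat12_7, bat12_8, bat12_9, bat12_10, bat12_11, bat12_12]
  response_range: [1, 5]
  scoring: mean
uwes3:
  items: [uwes3_1, uwes3_2, uwes3_3]
  response_range: [1, 5]
  scoring: mean
workload:
  items: [workload_1, workload_2, workload_3]
  response_range: [1, 5]
  scoring: mean
emotional_load:
  items: [emotional_load_1, emotional_load_2, emotional_load_3]
  response_range: [1, 5]
  scoring: mean
role_conflict:
  items: [role_conflict_1, role_conflict_2, role_conflict_3]
  response_range: [1, 5]
  scoring: mean
autonomy:
  items: [autonomy_1, autonomy_2, autonomy_3]
  response_range: [1, 5]
  scoring: mean
social_support:
  items: [social_support_1, social_support_2, social_support_3,
          social_support_4, social_support_5, social_support_6]
  response_range: [1, 5]
  scoring: mean
skills_use:
  items: [skills_use_1, skills_use_2, skills_use_3]
  response_range: [1, 5]
  scoring: mean
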