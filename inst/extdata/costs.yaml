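# Unit costs (Baht) for the testing-strategy comparison.
# Adjuvant therapy costs follow the institutional announcements:
# vaginal brachytherapy (intermediate), EBRT + brachytherapy
# (high-intermediate), chemoradiation (high); low risk receives none.
test_unit_costs:
  POLE: 4500
  MMR: 1420
  p53: 570
treatment_costs:
  low: 0
  intermediate: 53400
  high_intermediate: 127000
  high: 151722
# "move_to_high" prices each p53 escalation as high minus conventional;
# "explicit_override" reports the configured net for escalating strategies.
p53_upgrade_mode: explicit_override
therapy_change_override: 12288
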