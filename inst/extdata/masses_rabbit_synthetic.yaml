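# SYNTHETIC organ-mass table for a ~2.5-kg laboratory rabbit.
# Literature-style placeholder values for demonstration and testing;
# not an authoritative phantom. Units: kg.
species: rabbit
total_body_kg: 2.5
organ_masses_kg:
  liver: 0.090
  spleen: 0.003
  kidneys: 0.016
  lungs: 0.012
  red_marrow: 0.040
  muscle: 1.200
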