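# SYNTHETIC organ-mass table for a 70-kg adult human.
# Literature-style placeholder values for demonstration and testing;
# not an authoritative phantom. Units: kg.
species: human
total_body_kg: 70
organ_masses_kg:
  liver: 1.80
  spleen: 0.150
  kidneys: 0.310
  lungs: 1.20
  red_marrow: 1.17
  muscle: 28.0
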