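# Reference adult human (70 kg) for the flow-limited PBPK model.
# All flows are PLASMA flows (L/h); volumes in L. The liver receives the
# hepatic artery plus the portal (gut) outflow, so
#   flow_liver = hepatic_artery_flow + flow_gut
# and total cardiac plasma flow is the sum of hepatic artery, gut, kidney
# and rest flows. Tissue compositions are volume fractions of water,
# neutral lipid and phospholipid used for composition-based Kp prediction;
# plasma_composition is the reference phase.
species: human
bw_kg: 70
venous_plasma_volume_L: 2.0
arterial_plasma_volume_L: 1.0
hepatic_artery_flow_L_per_h: 13.2
gfr_L_per_h: 6.7
hepatocellularity_1e6_per_g: 110
liver_mass_g: 1800
plasma_composition:
  f_water: 0.945
  f_neutral_lipid: 0.0023
  f_phospholipid: 0.0013
tissues:
  gut:
    volume_L: 1.65
    flow_L_per_h: 49.5
    composition:
      f_water: 0.718
      f_neutral_lipid: 0.0487
      f_phospholipid: 0.0163
  liver:
    volume_L: 1.8
    flow_L_per_h: 62.7
    composition:
      f_water: 0.751
      f_neutral_lipid: 0.0348
      f_phospholipid: 0.0252
  kidney:
    volume_L: 0.31
    flow_L_per_h: 39.6
    composition:
      f_water: 0.783
      f_neutral_lipid: 0.0207
      f_phospholipid: 0.0162
  rest:
    volume_L: 61.0
    flow_L_per_h: 82.5
    composition:
      f_water: 0.63
      f_neutral_lipid: 0.10
      f_phospholipid: 0.02
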