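{
  "_comment": "Glucose minimal medium for the BiGG E. coli model iJR904. Uptake 10 mmol/gDCW/h glucose; NH4, H2O, SO4, O2, H+, phosphate and inorganic ions free at 1000. The diffusion_transport list is the package default (protein-free diffusion: CO2, O2, H2O, NH3); verify ids against your model version.",
  "substrate": "EX_glc__D_e",
  "substrate_bound": 10,
  "free": ["EX_nh4_e", "EX_h2o_e", "EX_so4_e", "EX_h_e", "EX_pi_e", "EX_fe2_e", "EX_k_e", "EX_na1_e"],
  "oxygen": "EX_o2_e",
  "aerobic": true,
  "biomass": "BIOMASS_Ecoli",
  "maintenance": ["ATPM"],
  "diffusion_transport": ["CO2t", "O2t", "H2Ot", "NH4t"],
  "molecular_weights": {"glucose": 180.16, "acetate": 60.05, "glycerol": 92.09, "ethanol": 46.07, "succinate": 118.09}
}
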