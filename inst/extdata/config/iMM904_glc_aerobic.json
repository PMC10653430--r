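{
  "_comment": "Glucose minimal medium for the BiGG S. cerevisiae model iMM904. Same uptake policy as the E. coli config; diffusion transports are the package default list.",
  "substrate": "EX_glc__D_e",
  "substrate_bound": 10,
  "free": ["EX_nh4_e", "EX_h2o_e", "EX_so4_e", "EX_h_e", "EX_pi_e", "EX_o2_e", "EX_fe2_e", "EX_k_e", "EX_na1_e"],
  "oxygen": "EX_o2_e",
  "aerobic": true,
  "biomass": "BIOMASS_SC4_bal",
  "maintenance": ["ATPM"],
  "diffusion_transport": ["CO2t", "O2t", "H2Ot", "NH4t"]
}
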