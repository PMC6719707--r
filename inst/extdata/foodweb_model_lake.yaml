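# Five-node temperate-lake model web: sediment, phytoplankton, zooplankton,
# forage fish, piscivorous fish in a linear pelagic chain. Same parameters
# as default_foodweb_config(); the sediment lipid_fraction is an
# organic-carbon proxy and the node never enters the TMF regression.
water_conc: 1.0e-4
gill_uptake_coeff: 150
diet_assimilation_eff: 0.8
egestion_ratio: 0.2
nodes:
  - id: sediment
    kind: sediment
    lipid_fraction: 0.02
  - id: phytoplankton
    kind: producer
    lipid_fraction: 0.01
  - id: zooplankton
    kind: invertebrate
    weight: 1.0e-5
    lipid_fraction: 0.01
    feeding_rate: 0.5
    growth_rate: 0.04
    diet:
      phytoplankton: 1.0
  - id: forage_fish
    kind: fish
    weight: 0.01
    lipid_fraction: 0.05
    feeding_rate: 0.05
    growth_rate: 0.005
    diet:
      zooplankton: 1.0
  - id: piscivorous_fish
    kind: fish
    weight: 1.0
    lipid_fraction: 0.08
    feeding_rate: 0.02
    growth_rate: 0.002
    diet:
      forage_fish: 1.0
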