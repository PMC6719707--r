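# Dataset metadata accompanying example_foodweb_synthetic.csv
baseline_species: species_01
baseline_tl: 2.0
enrichment_factor: 3.4
ecosystem: lake
latitude_class: temperate
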