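# Example monitoring-site context: a temperate lake monitored for PCB153
# in European perch, adjusted to the continental reference trophic level 4.
ecosystem: lake
latitude_class: temperate
target_species: Perca fluviatilis
chemical: PCB153
chemical_class: lipophilic
target_tl: 4
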