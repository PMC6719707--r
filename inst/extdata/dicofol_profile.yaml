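# Dicofol-like chemical profile: a data-poor organochlorine acaricide with
# no published TMF or BMF, but laboratory BCF data for carp. The BCF shown
# is a representative value inside the reported laboratory range
# (log BCF 3.49-4.32).
name: dicofol
log_kow: 5.02
bcf_ww: 3981.0717055349733   # 10^3.6 L/kg
bcf_species: carp
chemical_class: lipophilic
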