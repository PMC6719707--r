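study_id,chemical,tmf,ecosystem,latitude_class,species_list,tissue,basis,tl_range_width,n_obs,n_nonvertebrate_taxa,balance_index,diet_linkage_evidence,same_habitat,baseline_used,censored_fraction,single_season,includes_endotherms
lakeA_pcb153,PCB153,2.4,lake,temperate,Perca fluviatilis;Rutilus rutilus;Daphnia,whole_body,lipid_weight,2.3,48,4,0.4,gut_contents,TRUE,TRUE,0,TRUE,FALSE
lakeB_pcb153,PCB153,3.1,lake,temperate,Perca fluviatilis;Gammarus;Dreissena,whole_body,lipid_weight,2.1,36,3,0.45,d13c,TRUE,TRUE,0.05,TRUE,FALSE
river_pcb153,PCB153,1.8,river,temperate,Barbus barbus;Chironomidae,muscle_fillet,lipid_weight,2.0,30,2,0.6,none,FALSE,TRUE,0.3,FALSE,TRUE
marine_pfos,PFOS,3.8,marine,temperate,Gadus morhua;Mytilus edulis,whole_body,wet_weight,2.5,52,3,0.38,d13c,TRUE,TRUE,0,TRUE,FALSE
lake_pyrene,pyrene,0.6,lake,temperate,Perca fluviatilis;Daphnia;Dreissena,whole_body,lipid_weight,2.2,40,3,0.35,gut_contents,TRUE,TRUE,0.1,TRUE,FALSE
lake_bap,benzo[a]pyrene,0.45,lake,temperate,Perca fluviatilis;Daphnia;Gammarus,whole_body,lipid_weight,2.4,44,3,0.4,gut_contents,TRUE,TRUE,0.15,TRUE,FALSE
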