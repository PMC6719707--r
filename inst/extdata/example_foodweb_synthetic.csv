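"sample_id","species","taxon_group","endotherm","tissue","habitat","d15n","d13c","d34s","concentration","basis","lipid_fraction","water_fraction","detected","detection_limit","pool_size","season","location"
"S0001","species_01","zooplankton","FALSE","whole_body","pelagic","                 8","","","5.1560548629019998","wet_weight","0.050000000000000003","0.90000000000000002","TRUE","","                 1","summer","synthetic"
"S0002","species_01","zooplankton","FALSE","whole_body","pelagic","                 8","",""," 1.354005860964941","wet_weight","0.050000000000000003","0.90000000000000002","TRUE","","                 1","summer","synthetic"
"S0003","species_01","zooplankton","FALSE","whole_body","pelagic","                 8","","","2.5702094678771399","wet_weight","0.050000000000000003","0.90000000000000002","TRUE","","                 1","summer","synthetic"
"S0004","species_01","zooplankton","FALSE","whole_body","pelagic","                 8","","","3.0966261514806641","wet_weight","0.050000000000000003","0.90000000000000002","TRUE","","                 1","summer","synthetic"
"S0005","species_02","benthic_invertebrate","FALSE","whole_body","pelagic","9.6999999999999993","","","3.7396029218820468","wet_weight","0.050000000000000003","0.80000000000000004","TRUE","","                 1","summer","synthetic"
"S0006","species_02","benthic_invertebrate","FALSE","whole_body","pelagic","9.6999999999999993","","","2.6284979259474497","wet_weight","0.050000000000000003","0.80000000000000004","TRUE","","                 1","summer","synthetic"
"S0007","species_02","benthic_invertebrate","FALSE","whole_body","pelagic","9.6999999999999993","","","8.0352906903545147","wet_weight","0.050000000000000003","0.80000000000000004","TRUE","","                 1","summer","synthetic"
"S0008","species_02","benthic_invertebrate","FALSE","whole_body","pelagic","9.6999999999999993","","","2.6493984748514698","wet_weight","0.050000000000000003","0.80000000000000004","TRUE","","                 1","summer","synthetic"
"S0009","species_03","fish","FALSE","whole_body","pelagic","              11.4","","","16.128244755653512","wet_weight","0.050000000000000003","0.73999999999999999","TRUE","","                 1","summer","synthetic"
"S0010","species_03","fish","FALSE","whole_body","pelagic","              11.4","","","3.8304144017901325","wet_weight","0.050000000000000003","0.73999999999999999","TRUE","","                 1","summer","synthetic"
"S0011","species_03","fish","FALSE","whole_body","pelagic","              11.4","","","9.8519202493304192","wet_weight","0.050000000000000003","0.73999999999999999","TRUE","","                 1","summer","synthetic"
"S0012","species_03","fish","FALSE","whole_body","pelagic","              11.4","","","19.411254745619374","wet_weight","0.050000000000000003","0.73999999999999999","TRUE","","                 1","summer","synthetic"
"S0013","species_04","fish","FALSE","whole_body","pelagic","              13.1","","","2.1672887608441194","wet_weight","0.050000000000000003","0.73999999999999999","TRUE","","                 1","summer","synthetic"
"S0014","species_04","fish","FALSE","whole_body","pelagic","              13.1","","","4.6659315046971601","wet_weight","0.050000000000000003","0.73999999999999999","TRUE","","                 1","summer","synthetic"
"S0015","species_04","fish","FALSE","whole_body","pelagic","              13.1","","","5.1591551469274366","wet_weight","0.050000000000000003","0.73999999999999999","TRUE","","                 1","summer","synthetic"
"S0016","species_04","fish","FALSE","whole_body","pelagic","              13.1","","","8.7772831482508415","wet_weight","0.050000000000000003","0.73999999999999999","TRUE","","                 1","summer","synthetic"
"S0017","species_05","fish","FALSE","whole_body","pelagic","14.800000000000001","","","6.5737640278099221","wet_weight","0.050000000000000003","0.73999999999999999","TRUE","","                 1","summer","synthetic"
"S0018","species_05","fish","FALSE","whole_body","pelagic","14.800000000000001","","","1.2768896322752314","wet_weight","0.050000000000000003","0.73999999999999999","TRUE","","                 1","summer","synthetic"
"S0019","species_05","fish","FALSE","whole_body","pelagic","14.800000000000001","","","1.4823471011825315","wet_weight","0.050000000000000003","0.73999999999999999","TRUE","","                 1","summer","synthetic"
"S0020","species_05","fish","FALSE","whole_body","pelagic","14.800000000000001","",""," 19.91241755696306","wet_weight","0.050000000000000003","0.73999999999999999","TRUE","","                 1","summer","synthetic"
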