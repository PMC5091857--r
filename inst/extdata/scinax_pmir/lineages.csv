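lineage,nominal_name,has_morph_data,has_acoustic_data,source_note
Scinax_sp1,,TRUE,TRUE,undescribed lineage with voucher morphology and recorded calls
Scinax_sp2,,TRUE,TRUE,undescribed lineage with voucher morphology and recorded calls
Scinax_sp3,,TRUE,TRUE,undescribed lineage with voucher morphology and recorded calls
Scinax_sp4,,TRUE,TRUE,undescribed lineage with voucher morphology and recorded calls
Scinax_sp5,,TRUE,TRUE,undescribed lineage with voucher morphology and recorded calls
Scinax_sp6,,TRUE,TRUE,undescribed lineage with voucher morphology and recorded calls
Scinax_sp7,,TRUE,TRUE,undescribed lineage with voucher morphology and recorded calls
S_cruentommus_BRA,Scinax cruentommus,TRUE,TRUE,nominal species in the study area
S_aff_cruentommus_BRA,,TRUE,TRUE,divergent lineage close to S. cruentommus
S_chiquitanus_BRA,Scinax chiquitanus,TRUE,TRUE,nominal species; first record for Brazil
S_ruber_F,,FALSE,FALSE,merged central and east Madeira populations; no morphological or bioacoustic data
S_ruber_F_central,,FALSE,FALSE,distance-based split of S_ruber_F; no morphological or bioacoustic data
S_ruber_F_east,,FALSE,FALSE,distance-based split of S_ruber_F; no morphological or bioacoustic data
S_ruber_PM,,FALSE,FALSE,northern Purus-Madeira population; no morphological or bioacoustic data
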