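id,unit
sp1_01,Scinax_sp1
sp1_02,Scinax_sp1
sp2_01,Scinax_sp2
sp2_02,Scinax_sp2
sp3_01,Scinax_sp3
sp3_02,Scinax_sp3
sp4_01,Scinax_sp4
sp4_02,Scinax_sp4
sp5_01,Scinax_sp5
sp5_02,Scinax_sp5
sp6_01,Scinax_sp6
sp6_02,Scinax_sp6
sp7_01,Scinax_sp7
sp7_02,Scinax_sp7
cru_01,S_cruentommus_BRA
cru_02,S_cruentommus_BRA
affcru_01,S_aff_cruentommus_BRA
affcru_02,S_aff_cruentommus_BRA
chiq_01,S_chiquitanus_BRA
chiq_02,S_chiquitanus_BRA
rubF_01,S_ruber_F
rubF_02,S_ruber_F
rubPM_01,S_ruber_PM
rubPM_02,S_ruber_PM
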