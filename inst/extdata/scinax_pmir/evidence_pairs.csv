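lineage_a,lineage_b,morph_diff,acoustic_diff,reference_split,source_note
Scinax_sp1,S_cruentommus_BRA,yes,yes,unknown,calls and morphology diagnostic against the nominal species
Scinax_sp1,S_chiquitanus_BRA,yes,yes,unknown,calls and morphology diagnostic against the nominal species
Scinax_sp2,S_cruentommus_BRA,no,yes,unknown,advertisement call diagnostic
Scinax_sp2,S_chiquitanus_BRA,yes,yes,unknown,calls and morphology diagnostic
Scinax_sp3,S_cruentommus_BRA,yes,yes,unknown,calls and morphology diagnostic
Scinax_sp3,S_chiquitanus_BRA,yes,no,unknown,morphology diagnostic
Scinax_sp4,S_cruentommus_BRA,no,yes,unknown,advertisement call diagnostic
Scinax_sp4,S_chiquitanus_BRA,no,yes,unknown,advertisement call diagnostic
Scinax_sp5,S_cruentommus_BRA,yes,yes,unknown,calls and morphology diagnostic
Scinax_sp5,S_chiquitanus_BRA,yes,yes,unknown,calls and morphology diagnostic
Scinax_sp6,S_cruentommus_BRA,yes,yes,unknown,calls and morphology diagnostic
Scinax_sp6,S_chiquitanus_BRA,no,yes,unknown,advertisement call diagnostic
Scinax_sp7,S_cruentommus_BRA,yes,yes,unknown,calls and morphology diagnostic
Scinax_sp7,S_chiquitanus_BRA,yes,yes,unknown,calls and morphology diagnostic
S_aff_cruentommus_BRA,S_cruentommus_BRA,no,no,unknown,not differentiable from the nominal species by morphology or calls
S_ruber_F_central,S_ruber_F_east,unknown,unknown,unknown,no morphological or bioacoustic evidence for the distance-based split
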