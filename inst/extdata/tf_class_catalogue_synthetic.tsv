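class	identifiers
basic_helix_loop_helix	PTHR19184,PTHR40554
basic_leucine_zipper	PTHR25147,PTHR85617
homeodomain	PTHR30828,PTHR97920,PTHR90777,PTHR10356
paired_box	PTHR76594,PTHR41273
pou_domain	PTHR99863,PTHR15371
forkhead_winged_helix	PTHR29304,PTHR91028
high_mobility_group	PTHR72801,PTHR44287
ets_domain	PTHR13007,PTHR88717,PTHR68692,PTHR39852
rel_homology	PTHR47511,PTHR67534,PTHR57420,PTHR22206
stat_domain	PTHR45507,PTHR68981
p53_domain	PTHR73054,PTHR89660
runt_domain	PTHR28695,PTHR32373
t_box	PTHR17931,PTHR37414,PTHR21536
mads_box	PTHR27008,PTHR36771,PTHR17088
nuclear_receptor	PTHR46259,PTHR20412
zinc_finger_c2h2	PTHR84155,PTHR60717
zinc_finger_gata	PTHR35260,PTHR12714
zinc_finger_nuclear_hormone	PTHR52097,PTHR81633,PTHR10275
zinc_finger_dhhc	PTHR42910,PTHR69704,PTHR23008
lim_homeodomain	PTHR79208,PTHR13179
cut_homeodomain	PTHR59425,PTHR99499,PTHR18121,PTHR83658
prospero_homeodomain	PTHR39385,PTHR16458,PTHR71611
tale_homeodomain	PTHR92718,PTHR19377
sine_oculis	PTHR16550,PTHR29947,PTHR88207
nk_homeodomain	PTHR73125,PTHR47660,PTHR85203,PTHR14844
hox_related	PTHR17940,PTHR85130,PTHR14622,PTHR17625
otx_related	PTHR66886,PTHR18611,PTHR87599
pax_related	PTHR57301,PTHR80236,PTHR45428
irx_related	PTHR78225,PTHR94749,PTHR56503
grainyhead	PTHR52358,PTHR92296
smad_mh1	PTHR37512,PTHR53948,PTHR40151
tea_domain	PTHR64313,PTHR82068,PTHR21904
arid_bright	PTHR43211,PTHR38450,PTHR32475
cold_shock	PTHR55324,PTHR67240,PTHR91241
sand_domain	PTHR51462,PTHR22677,PTHR88058,PTHR61159
heat_shock_factor	PTHR37186,PTHR57677
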