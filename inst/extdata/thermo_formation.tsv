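## Standard Gibbs energies and enthalpies of formation at 298.15 K,
## anaerobic-microbiology convention (aqueous solutes at 1 M, gases at 1 atm,
## water as pure liquid, H+ as the chemical species; pH-7 transformed values
## are obtained by evaluating reactions at H+ activity 1e-7).
## Values compiled from the classical anaerobic-energetics tables
## (Thauer/Jungermann/Decker-style compilation) and standard reference data.
species_id	phase	dGf0_kj_mol	dHf0_kj_mol	note
h2_g	gas	0	0	hydrogen gas
h2_aq	aqueous	17.6	-4.2	dissolved hydrogen
co2_g	gas	-394.36	-393.51	carbon dioxide gas
co2_aq	aqueous	-386.02	-413.26	dissolved CO2
hco3_aq	aqueous	-586.85	-691.99	bicarbonate
ch4_g	gas	-50.75	-74.81	methane gas
ch4_aq	aqueous	-34.39	-89.04	dissolved methane
h2o_l	aqueous	-237.18	-285.83	liquid water (activity 1)
acetate_aq	aqueous	-369.41	-486.01	acetate anion
formate_aq	aqueous	-351.04	-425.55	formate anion
h_plus	aqueous	0	0	proton
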