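# Calibration scheme for the mitochondria-encoded data set (bounds in Ma,
# soft tails 2.5% each side).  The `taxa` column carries representative
# members of each calibrated clade; replace them with labels matching your
# own tree before use.
clade_name	taxa	group	t_min	t_max	p_lower	p_upper	tags
crown_angiosperms	Arabidopsis_thaliana;Oryza_sativa	crown	125	250	0.025	0.025	phanerozoic
crown_land_plants	Arabidopsis_thaliana;Physcomitrella_patens	crown	450	509	0.025	0.025	phanerozoic
total_Florideophyceae	Chondrus_crispus;Gracilaria_gracilis	total	550	1891	0.025	0.025	proterozoic_max;max_1891
total_red_algae	Chondrus_crispus;Cyanidioschyzon_merolae	total	1033	1891	0.025	0.025	proterozoic;max_1891
root	Rickettsia_prowazekii;Arabidopsis_thaliana	crown	1000	3000	0.025	0.025	root
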