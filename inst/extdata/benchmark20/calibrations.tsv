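clade_name	taxa	group	t_min	t_max	p_lower	p_upper	tags
cal_node_31	H4;H8;H5;H10;H2;H1;H7;H9;H6;H3	crown	1371.8185248754	2856.16486130077	0.025	0.025	
cal_node_38	H6;H3	crown	46.9601265616049	95.7697169431801	0.025	0.025	
root	S8;S7;S4;S2;S6;S3;S1;S5;S9;S10;H8;H5;H4;H10;H2;H6;H3;H1;H7;H9	crown	1000	3000	0.025	0.025	root
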