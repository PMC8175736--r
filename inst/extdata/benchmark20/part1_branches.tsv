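branch	child_node	b_hat	gradient
1	22	0.186592333876038	0
2	23	0.231971775074892	0
3	24	0.131292396738862	0
4	1	0.217845382805602	0
5	2	0.404119798941806	0
6	25	0.128222417807172	0
7	3	0.159556870831444	0
8	26	0.0141021769893198	0
9	4	0.173805497098676	0
10	27	0.0954604405039975	0
11	5	0.0862418058802913	0
12	6	0.0864687991062323	0
13	28	0.193353531683077	0
14	29	0.14498619730269	0
15	7	0.448646710946375	0
16	30	0.78176103739811	0
17	8	0.0285302963505955	0
18	9	0.0345442744548688	0
19	10	0.463390543483033	0
20	31	0.162948058668941	0
21	32	0.508850406783036	0
22	33	0.07477215817053	0
23	11	0.0316353721760292	0
24	12	0.0281935874965399	0
25	13	0.0983322159604743	0
26	34	0.0237940893749654	0
27	35	0.40268881883152	0
28	14	0.0637131165183702	0
29	15	0.0744900956659614	0
30	36	0.363348499239745	0
31	37	0.197664321740155	0
32	38	0.129155392318801	0
33	16	0.0269140355333197	0
34	17	0.0199145377427053	0
35	18	0.160307810828876	0
36	39	0.260008663458728	0
37	19	0.098030794350296	0
38	20	0.082554940329353	0
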