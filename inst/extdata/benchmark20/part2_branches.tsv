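branch	child_node	b_hat	gradient
1	22	0.190845345508992	0
2	23	0.154537897467256	0
3	24	0.113392525068289	0
4	1	0.266261162270674	0
5	2	0.38851833973116	0
6	25	0.172160545611087	0
7	3	0.189661420168834	0
8	26	0.00955303886239411	0
9	4	0.157268297264958	0
10	27	0.0866426852067502	0
11	5	0.0776318522644488	0
12	6	0.0861933573368251	0
13	28	0.161029272118427	0
14	29	0.173219948351853	0
15	7	0.355386494696648	0
16	30	0.650220160234174	0
17	8	0.0372500678060752	0
18	9	0.0357114502605041	0
19	10	0.574232886613962	0
20	31	0.141886170388327	0
21	32	0.421795883518829	0
22	33	0.0668668928999486	0
23	11	0.0271140531446664	0
24	12	0.0299540579503335	0
25	13	0.105193698916936	0
26	34	0.024123645772784	0
27	35	0.359086128741664	0
28	14	0.0664082553774105	0
29	15	0.0607736254786283	0
30	36	0.330252402647916	0
31	37	0.22402431335583	0
32	38	0.129982281471578	0
33	16	0.0270246359173334	0
34	17	0.0261569874781432	0
35	18	0.137635620416824	0
36	39	0.272266445984516	0
37	19	0.0892580298245887	0
38	20	0.0997862448861463	0
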