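{"ages":[0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,2500.0000000001,1980.2513364703,1400.021889042,980.992580035,770.6603103249,715.8127445814,336.4192551965,1586.1156339205,1244.9992037652,43.6193740682002,2066.7917852989,390.8241453805,110.5682881795,1987.6177444497,412.6487435644,950.676373078,407.2433105488,71.6060085667,247.3114107932],"branch_rates":[0.000346728995011196,0.000317986398177854,0.000274844084190878,0.000224934318582625,0.000379120149833464,0.000259692912747064,0.000227419084253035,0.000232605750974838,0.00023157658978372,0.000250237922480665,0.000221873570164393,0.000266168985016887,0.000429597303170996,0.000462377203686847,0.000313431584613614,0.000591225627489695,0.000785474221691041,0.000803826080319466,0.000382913866686033,0.000338425949173502,0.000316109770998238,0.000271825154915057,0.000249614310627769,0.000253637642133956,0.000283041503792396,0.000319649436081415,0.000236566273814261,0.000150021787120021,0.000155112729577988,0.000328113303945246,0.000369674798533285,0.00038836392017403,0.000384537207304073,0.000339710969663741,0.000345768526486554,0.000370556509749804,0.000367198226735118,0.000392195735288935],"mu":0.000303991532224468,"sigma2":0.000224891452695327,"n_partitions":2}
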