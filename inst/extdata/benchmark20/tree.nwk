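((((S8:980.99258,S7:980.99258):419.029309,(S4:770.6603103,(S2:715.8127446,(S6:336.4192552,S3:336.4192552):379.3934894):54.84756574):629.3615787):580.2294474,((S1:1244.999204,(S5:43.61937407,S9:43.61937407):1201.37983):341.1164302,S10:1586.115634):394.1357025):519.7486635,(((H8:110.5682882,H5:110.5682882):280.2558572,H4:390.8241454):1675.96764,((H10:412.6487436,H2:412.6487436):1574.969001,(((H6:71.60600857,H3:71.60600857):335.637302,H1:407.2433105):543.4330625,(H7:247.3114108,H9:247.3114108):703.3649623):1036.941371):79.17404085):433.2082147);
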