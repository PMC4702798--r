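label,x,y,z,dfg_out_specific,n_members
I1,6.008468923255291,1.0269844695849875,4.010398832996138,FALSE,40
I2,6.962785092067466,-1.0273213740622236,-2.030285853861179,FALSE,40
I3,3.9948660159563176,1.9977717942241169,-4.008936219263128,FALSE,40
I4,-0.9940416417339649,-1.012015992374915,-4.529442084240578,FALSE,40
I5,-3.018470230751348,-1.483413386937588,-2.993052975022159,FALSE,40
I6,-0.030433137613158873,2.008665688997676,4.995868446027921,FALSE,40
I7,-2.024388383163818,-2.9535294460599113,4.999523915838682,FALSE,40
I8,1.9875480082921406,-3.00190531453189,1.9827794788378044,FALSE,40
I9,-6.9916018125296056,-2.0121989122997586,1.0262286017657816,FALSE,40
I10,-5.983910414344866,2.9619897049445347,-5.020996602367773,FALSE,40
I11,4.993856257859479,3.993562025265767,-0.9853817145160155,FALSE,40
O1,-5.99733377419653,2.5112781862855242,1.529277630002737,TRUE,40
O2,-7.9721157946100965,0.9613648263972673,-1.5234457097543763,TRUE,40
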