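branch	length	lysin	vezp14_zpn
b1	0.0772291754141188	2.73671706973842	0
b2	0.260518314508292	0.666082362669715	1.52039407977169
b3	0.0856040751491762	1.16941486645281	0.153932298303254
b4	0.0307976401626483	0.339136860878053	1.67270520340425
b5	0.109109305833916	1.02963010981271	0.596801398200661
b6	0.432208196142845	0.602103201958494	1.9914945438523
b7	0.323281207274074	3.74292199803853	0
b8	0.0370998483223276	1.06813087003244	0.754790691678648
b9	0.0470469213569683	0.348514268264217	1.6679038212038
b10	0.0335420045186908	0.210925118256675	1.56815154370145
b11	0.118174789980298	2.65707622500367	0
b12	0.077330585121041	2.20290644151364	0
b13	0.094721311354021	2.08076866851152	0
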