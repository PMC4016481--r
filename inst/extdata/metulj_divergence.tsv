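subfamily	mean_distance	sd	range_low	range_high	time_low_mya	time_high_mya
Metulj-0_Hm	0.20747	0.06289	0.14458	0.27036	7.6	14.2
Metulj-1_Hm	0.17328	0.07409	0.09919	0.24737	5.2	13.0
Metulj-2_Hm	0.15970	0.09649	0.06321	0.25619	3.3	13.4
Metulj-5_Hm	0.20597	0.06798	0.13799	0.27395	7.2	14.4
Metulj-6_Hm	0.20272	0.07116	0.13156	0.27388	6.9	14.3
Metulj-7_Hm	0.24241	0.06665	0.17576	0.30906	9.2	16.2
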