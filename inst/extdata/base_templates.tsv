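base	atom	element	role	x	y	z
A	P	P	backbone	-7.39633105	-5.86443614	-3.27411587
A	OP1	O	backbone	-7.11803981	-7.30666187	-3.09785226
A	OP2	O	backbone	-7.01222653	-5.42233786	-4.77177204
A	O5'	O	backbone	-6.52160663	-5.01600598	-2.22212671
A	C5'	C	backbone	-5.15049250	-5.30442957	-2.49858827
A	C4'	C	sugar	-4.43743355	-5.68603808	-1.20012580
A	O4'	O	sugar	-3.00774240	-5.51394645	-1.33025168
A	C3'	C	sugar	-4.81885130	-4.70855403	-0.05933694
A	O3'	O	backbone	-6.02209362	-5.12642358	0.58979086
A	C2'	C	sugar	-3.60563319	-4.83230451	0.89277887
A	C1'	C	sugar	-2.48000000	-5.38819097	0.00000000
A	N9	N	ring	-1.34067142	-4.46638366	-0.00000000
A	C8	C	ring	-0.02370415	-4.81317048	0.00064902
A	N7	N	ring	0.71749333	-3.74368494	0.00165507
A	C5	C	ring	-0.07500663	-2.64502655	0.00171544
A	C6	C	ring	0.15571649	-1.25945437	0.00256196
A	N6	N	base	1.44498296	-0.75641923	0.00362422
A	N1	N	ring	-0.89274321	-0.44256829	0.00231927
A	C2	C	ring	-2.12510952	-0.91340690	0.00130896
A	N3	N	ring	-2.38989885	-2.20241263	0.00049003
A	C4	C	ring	-1.40589467	-3.09630842	0.00065334
A	H61	H	hpolar	1.59171660	0.20229502	0.00420187
A	H62	H	hpolar	2.20236655	-1.36330086	0.00379103
C	P	P	backbone	-7.40486247	-5.80168877	-3.27411587
C	OP1	O	backbone	-7.15543266	-7.24918517	-3.09785226
C	OP2	O	backbone	-7.01200445	-5.36735048	-4.77177204
C	O5'	O	backbone	-6.51336665	-4.97089893	-2.22212671
C	C5'	C	backbone	-5.14828679	-5.28665057	-2.49858827
C	C4'	C	sugar	-4.44299204	-5.68242505	-1.20012580
C	O4'	O	sugar	-3.01014887	-5.53892331	-1.33025168
C	C3'	C	sugar	-4.80481018	-4.69751785	-0.05933694
C	O3'	O	backbone	-6.01615869	-5.09127139	0.58979086
C	C2'	C	sugar	-3.59430580	-4.84547553	0.89277887
C	C1'	C	sugar	-2.48000000	-5.42373364	0.00000000
C	N1	N	ring	-1.32318250	-4.52540620	0.00000000
C	C2	C	ring	-1.51045257	-3.19411067	-0.00002488
C	O2	O	base	-2.64601834	-2.74774225	-0.00000169
C	N3	N	ring	-0.47641871	-2.35437495	-0.00007442
C	C4	C	ring	0.76796747	-2.81199057	-0.00010055
C	N4	N	base	1.82845354	-1.93562242	-0.00015171
C	C5	C	ring	0.99776272	-4.20277674	-0.00007556
C	C6	C	ring	-0.06301467	-5.04321849	-0.00002521
C	H41	H	hpolar	1.66638916	-0.97940728	-0.00016876
C	H42	H	hpolar	2.73745464	-2.27377113	-0.00017070
G	P	P	backbone	-7.40486247	-5.80168877	-3.27411587
G	OP1	O	backbone	-7.15543266	-7.24918517	-3.09785226
G	OP2	O	backbone	-7.01200445	-5.36735048	-4.77177204
G	O5'	O	backbone	-6.51336665	-4.97089893	-2.22212671
G	C5'	C	backbone	-5.14828679	-5.28665057	-2.49858827
G	C4'	C	sugar	-4.44299204	-5.68242505	-1.20012580
G	O4'	O	sugar	-3.01014887	-5.53892331	-1.33025168
G	C3'	C	sugar	-4.80481018	-4.69751785	-0.05933694
G	O3'	O	backbone	-6.01615869	-5.09127139	0.58979086
G	C2'	C	sugar	-3.59430580	-4.84547553	0.89277887
G	C1'	C	sugar	-2.48000000	-5.42373364	0.00000000
G	N9	N	ring	-1.32373634	-4.52583629	0.00000000
G	C8	C	ring	-0.01222117	-4.90034375	-0.00030338
G	N7	N	ring	0.74876551	-3.84436047	-0.00077331
G	C5	C	ring	-0.02695081	-2.73292688	-0.00079928
G	C6	C	ring	0.24141918	-1.34408037	-0.00119961
G	O6	O	base	1.38775160	-0.92993591	-0.00163593
G	N1	N	ring	-0.80427078	-0.48917044	-0.00108613
G	C2	C	ring	-2.08122650	-0.96299587	-0.00059721
G	N2	N	base	-3.12320896	-0.07075184	-0.00049344
G	N3	N	ring	-2.34367245	-2.25062888	-0.00022200
G	C4	C	ring	-1.36076106	-3.15819493	-0.00030467
G	H1	H	hpolar	-0.64438442	0.46789794	-0.00135456
G	H21	H	hpolar	-4.03788556	-0.39315502	-0.00014716
G	H22	H	hpolar	-2.94551856	0.88298117	-0.00076639
T	P	P	backbone	-7.39633105	-5.86443614	-3.27411587
T	OP1	O	backbone	-7.11803981	-7.30666187	-3.09785226
T	OP2	O	backbone	-7.01222653	-5.42233786	-4.77177204
T	O5'	O	backbone	-6.52160663	-5.01600598	-2.22212671
T	C5'	C	backbone	-5.15049250	-5.30442957	-2.49858827
T	C4'	C	sugar	-4.43743355	-5.68603808	-1.20012580
T	O4'	O	sugar	-3.00774240	-5.51394645	-1.33025168
T	C3'	C	sugar	-4.81885130	-4.70855403	-0.05933694
T	O3'	O	backbone	-6.02209362	-5.12642358	0.58979086
T	C2'	C	sugar	-3.60563319	-4.83230451	0.89277887
T	C1'	C	sugar	-2.48000000	-5.38819097	0.00000000
T	N1	N	ring	-1.36511328	-4.48615907	-0.00000000
T	C2	C	ring	-1.55505857	-3.08769025	0.00023653
T	O2	O	base	-2.66194501	-2.54579223	0.00006860
T	N3	N	ring	-0.37920089	-2.33027597	0.00068589
T	C4	C	ring	0.92194290	-2.80981981	0.00091529
T	O4	O	base	1.91321152	-2.08525944	0.00131160
T	C5	C	ring	1.04144470	-4.29220993	0.00064400
T	C7	C	base	2.41273776	-4.88760645	0.00086748
T	C6	C	ring	-0.08287551	-5.02031758	0.00021355
T	H3	H	hpolar	-0.49149538	-1.32076324	0.00086287
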