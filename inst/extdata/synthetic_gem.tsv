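source	target	flags
X100	1000	0
X101	1010	0
X102	1020	0
X103	1030	0
X104	1040	0
X105	1050	0
X106	1060	0
X107	1070	0
X108	1080	0
X109	1090	0
X110	1100	0
X111	1110	0
X112	1120	0
X113	1130	0
X114	1140	0
X115	1150	0
X116	1160	0
X117	1170	0
X118	1180	0
X119	1190	0
X120	1200	0
X121	1210	0
X122	1220	0
X123	1230	0
X124	1240	0
X125	1250	0
X126	1260	0
X127	1270	0
X128	1280	0
X129	1290	0
X130	1300	0
X131	1310	0
X132	1320	0
X133	1330	0
X134	1340	0
X135	1350	0
X136	1360	0
X137	1370	0
X138	1380	0
X139	1390	0
X250	2500	0
X401	4010	0
X628	6280	0
X655	6550	0
X758	7580	0
X796	7960	0
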