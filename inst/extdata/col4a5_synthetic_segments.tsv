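# Synthetic COL4A5-like chain architecture (NOT the real NM_033380.3 coordinates).
# 23 local collagenous regions, 460 Gly slots, 46 non-collagenous boundary Gly.
kind	start	end
amino_terminus	1	41
collagenous	42	68
interruption	69	71
collagenous	72	113
interruption	114	118
collagenous	119	181
interruption	182	188
collagenous	189	266
interruption	267	275
collagenous	276	311
interruption	312	322
collagenous	323	415
interruption	416	417
collagenous	418	468
interruption	469	472
collagenous	473	541
interruption	542	547
collagenous	548	571
interruption	572	579
collagenous	580	663
interruption	664	673
collagenous	674	718
interruption	719	730
collagenous	731	790
interruption	791	793
collagenous	794	826
interruption	827	831
collagenous	832	930
interruption	931	937
collagenous	938	994
interruption	995	1003
collagenous	1004	1081
interruption	1082	1092
collagenous	1093	1119
interruption	1120	1121
collagenous	1122	1193
interruption	1194	1197
collagenous	1198	1245
interruption	1246	1251
collagenous	1252	1341
interruption	1342	1349
collagenous	1350	1379
interruption	1380	1389
collagenous	1390	1497
interruption	1498	1509
collagenous	1510	1575
carboxyl_terminus	1576	1804
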