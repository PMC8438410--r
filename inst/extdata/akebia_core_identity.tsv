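accession	identity
TJ2	D1002322100
TJ174	3A00232D001
TJ427	D20DDBADA0B
TJ572	42A00123201
TJ703	D320AD32A0A
TJ5	202023AA10B
TJ179	4300213200A
TJ434	D3DD02BD20B
TJ573	32200A2320B
TJ727	3220402100A
TJ7	20A021A1100
TJ181	40004322001
TJ446	31020D32201
TJ575	DD20D3AD10A
TJ735	2222132D00A
TJ9	B0002AD2000
TJ208	BB00322D00A
TJ448	DFD20D2220A
TJ582	F110DA0220A
TJ741	AD20AA2200B
TJ19	DA0032D110A
TJ209	FF00333200A
TJ450	3A0203D2A0A
TJ585	3320DA12001
TJ751	2230DD2D00B
TJ24	B02012B100A
TJ216	2000232A00B
TJ453	D2B20D32201
TJ594	02002410001
TJ779	AA3122BD00A
TJ27	22202D3AA0B
TJ217	DA00223200B
TJ455	DD030B33201
TJ597	2120220D00B
TJ786	11311D2200A
TJ28	AD0033A200A
TJ259	4123D222221
TJ478	02D20332201
TJ603	220012A2200
TJ787	AAA12223001
TJ32	DD002D22A00
TJ264	3AA1222321B
TJ480	A414023020A
TJ606	D130AF2D00A
TJ791	3D1121A200A
TJ34	C220132B00A
TJ265	EA21A12211A
TJ491	02101223A0C
TJ608	0120B22DA0A
TJ794	D3111AAD00A
TJ39	D0200B32000
TJ270	3132A23D21B
TJ496	A2102A2230A
TJ609	A230AB2220A
TJ802	0BA0022220A
TJ48	33A00D21000
TJ284	3320131221A
TJ498	AA30222DD0B
TJ613	3D20032A000
TJ806	0A30022210A
TJ49	F3000221201
TJ295	BAA213D112A
TJ499	A2102322D0B
TJ616	3B20A2BB10A
TJ813	01A0A2D210A
TJ59	3D00232A000
TJ296	D3A01321211
TJ502	DD102222D0A
TJ629	421002A220A
TJ826	0FA0A32D10A
TJ63	C2202BA3100
TJ308	2D10DD3121A
TJ509	22A02B3D30B
TJ640	F3200421003
TJ832	0DA01DA020A
TJ84	22000A23B2A
TJ311	D222332101B
TJ510	A3202D22D0A
TJ653	2120DA3320A
TJ837	0A40B2A010A
TJ89	EAA04AA221A
TJ323	220A12BA000
TJ512	BA3013A3A0A
TJ655	AD202A1020A
TJ852	03D0033D10A
TJ97	21F00BB2031
TJ329	A20DAC2D00D
TJ515	0A20223230A
TJ663	03201A2320A
TJ858	0230032020D
TJ102	2D2002A220A
TJ342	C2AF03BF001
TJ518	BD102BDDA01
TJ667	2120222210A
TJ861	0130D33010A
TJ105	2320022212A
TJ348	2A430E3300A
TJ521	211023B2D0A
TJ668	121032ABA0A
TJ867	02002233301
TJ109	4130022A011
TJ349	2A230B33001
TJ522	AA302DB2D0A
TJ669	2B20BA30D0A
TJ873	0240012210B
TJ114	EFF0032D22A
TJ359	32230AA3001
TJ524	03202ABDA0A
TJ670	3330113020A
TJ875	0DD0032210A
TJ116	3030032211B
TJ371	322A1A2A000
TJ529	23A0222D201
TJ671	01300320D0A
TJ882	BAA03D3100A
TJ124	4130423E010
TJ374	024D0FDD00D
TJ534	0A202B3DA01
TJ676	A3002113A0A
TJ890	2A2012A200A
TJ131	A200A2D211A
TJ380	A2320F3200A
TJ545	332021A230A
TJ687	302011D020A
TJ895	2A202A2A00A
TJ132	EDA002A2230
TJ381	D21300B3000
TJ546	2A102322D0A
TJ690	23302422202
TJ899	10303D2300A
TJ137	DFD03DD202A
TJ394	B20DDFDD00A
TJ552	0220023DA0B
TJ692	B34022AD30A
TJ930	2C302FD200A
TJ139	BF4002D2231
TJ397	C2024EA200D
TJ554	011002A330B
TJ693	20200DA000A
TJ932	2A30A020001
TJ152	2300032211A
TJ398	EA322EB200A
TJ557	2110023230A
TJ696	02101D3B200
TJ938	2A10132000A
TJ153	2A2002AB02A
TJ413	1A2401D4102
TJ561	2A1001D100A
TJ697	2200A03220A
TJ942	31B0343300B
TJ160	33D0023202A
TJ414	D233022320A
TJ562	ED302A0A10B
TJ698	213023B2201
TJ944	2A102DB300A
TJ166	3200122A00A
TJ421	3D2D03DD301
TJ567	31103D02200
TJ699	3B3042D2A00
TJ945	1D10302400A
TJ173	2A00242200A
TJ422	21010D3110A
TJ568	FA2041A2100
TJ701	23302D32A00
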