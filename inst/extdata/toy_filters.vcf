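##fileformat=VCFv4.2
##source=ChelonScan toy filter fixture (synthetic, hand-constructed)
##contig=<ID=toy_1,length=10000>
##INFO=<ID=FS,Number=1,Type=Float,Description="Fisher strand bias">
##INFO=<ID=QD,Number=1,Type=Float,Description="Quality by depth">
##INFO=<ID=MQ,Number=1,Type=Float,Description="RMS mapping quality">
##INFO=<ID=MQRankSum,Number=1,Type=Float,Description="Mapping quality rank sum">
##INFO=<ID=ReadPosRankSum,Number=1,Type=Float,Description="Read position rank sum">
##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">
#CHROM	POS	ID	REF	ALT	QUAL	FILTER	INFO	FORMAT	S1
toy_1	100	r01	A	G	100	.	FS=1;QD=20;MQ=60;MQRankSum=0;ReadPosRankSum=0	GT	0/1
toy_1	200	r02	C	T	59.9	.	FS=1;QD=20;MQ=60;MQRankSum=0;ReadPosRankSum=0	GT	0/1
toy_1	300	r03	G	A	100	.	FS=60.5;QD=20;MQ=60;MQRankSum=0;ReadPosRankSum=0	GT	0/1
toy_1	400	r04	T	C	100	.	FS=60;QD=20;MQ=60;MQRankSum=0;ReadPosRankSum=0	GT	0/1
toy_1	500	r05	A	T	100	.	FS=1;QD=1.5;MQ=60;MQRankSum=0;ReadPosRankSum=0	GT	0/1
toy_1	600	r06	C	G	100	.	FS=1;QD=2;MQ=60;MQRankSum=0;ReadPosRankSum=0	GT	0/1
toy_1	700	r07	G	T	100	.	FS=1;QD=20;MQ=39;MQRankSum=0;ReadPosRankSum=0	GT	0/1
toy_1	800	r08	T	A	100	.	FS=1;QD=20;MQ=60;MQRankSum=-25;ReadPosRankSum=0	GT	0/1
toy_1	900	r09	A	C	100	.	FS=1;QD=20;MQ=60;MQRankSum=-12.5;ReadPosRankSum=0	GT	0/1
toy_1	1000	r10	C	A	100	.	FS=1;QD=20;MQ=60;MQRankSum=0;ReadPosRankSum=-9	GT	0/1
toy_1	1100	r11	G	C	100	.	FS=1;QD=20;MQ=60;MQRankSum=0;ReadPosRankSum=-8	GT	0/1
toy_1	1200	r12	T	A,G	100	.	FS=1;QD=20;MQ=60;MQRankSum=0;ReadPosRankSum=0	GT	1/2
toy_1	1300	r13	AT	A	80	.	FS=1;QD=20;MQ=60;MQRankSum=0;ReadPosRankSum=0	GT	0/1
toy_1	1303	r14	G	A	100	.	FS=1;QD=20;MQ=60;MQRankSum=0;ReadPosRankSum=0	GT	0/1
toy_1	1306	r15	C	T	100	.	FS=1;QD=20;MQ=60;MQRankSum=0;ReadPosRankSum=0	GT	0/1
toy_1	1400	r16	G	GA	50	.	FS=1;QD=20;MQ=60;MQRankSum=0;ReadPosRankSum=0	GT	0/1
toy_1	1402	r17	T	G	100	.	FS=1;QD=20;MQ=60;MQRankSum=0;ReadPosRankSum=0	GT	0/1
toy_1	1500	r18	A	G	100	.	.	GT	0/1
toy_1	1600	r19	C	T	60	.	FS=1;QD=20;MQ=60;MQRankSum=0;ReadPosRankSum=0	GT	0/1
toy_1	1700	r20	G	A	10	.	FS=1;QD=1;MQ=60;MQRankSum=0;ReadPosRankSum=0	GT	0/1
toy_1	1800	r21	T	C	100	.	FS=1;QD=20;MQ=40;MQRankSum=0;ReadPosRankSum=0	GT	0/1
toy_1	1900	r22	A	T	100	.	FS=70	GT	0/1
toy_1	2000	r23	C	G	.	.	FS=1;QD=20;MQ=60;MQRankSum=0;ReadPosRankSum=0	GT	0/1
toy_1	2100	r24	G	T	100	.	FS=1;QD=20;MQ=60;MQRankSum=0;ReadPosRankSum=0	GT	0/1
toy_1	2105	r25	T	A	100	.	FS=1;QD=20;MQ=60;MQRankSum=0;ReadPosRankSum=0	GT	0/1
toy_1	2110	r26	T	TTT	61	.	FS=1;QD=20;MQ=60;MQRankSum=0;ReadPosRankSum=0	GT	0/1
toy_1	2200	r27	A	C	100	.	FS=1;QD=20;MQ=60;MQRankSum=-20.5;ReadPosRankSum=0	GT	0/1
toy_1	2300	r28	C	A	100	.	FS=1;QD=25;MQ=60;MQRankSum=0;ReadPosRankSum=0	GT	0/1
toy_1	2400	r29	G	C	100	.	FS=1;QD=20;MQ=60;MQRankSum=0;ReadPosRankSum=-7.9	GT	0/1
toy_1	2500	r30	T	G	75	.	FS=1;QD=20;MQ=55;MQRankSum=0;ReadPosRankSum=0	GT	0/1
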