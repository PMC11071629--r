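monkey	scene	value	n	mean_rt_ms	sd_ms	ci_lo	ci_hi
C	1	good	1428	160.9	21.6	159.7	162.0
C	2	good	1443	162.6	22.4	161.5	163.8
C	3	good	1452	169.4	22.1	168.3	170.5
C	4	good	1419	165.5	21.4	164.4	166.7
C	1	bad	1076	234.3	46.7	231.5	237.1
C	2	bad	1076	240.0	46.0	237.2	242.7
C	3	bad	1247	215.0	50.3	212.2	217.8
C	4	bad	1205	221.3	52.3	218.8	225.1
S	1	good	1466	174.6	20.8	173.5	175.6
S	2	good	1482	179.1	22.0	178.0	180.2
S	3	good	1490	184.5	21.4	183.4	185.6
S	4	good	1476	186.9	24.3	185.7	188.2
S	1	bad	1194	302.1	42.5	299.7	304.6
S	2	bad	1054	311.9	41.2	309.4	314.4
S	3	bad	1174	291.2	51.8	288.2	294.2
S	4	bad	1120	299.9	47.4	297.1	302.6
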