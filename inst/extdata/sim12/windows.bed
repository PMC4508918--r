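chr1	0	1000000	L000001
chr1	1000000	2000000	L000002
chr1	2000000	3000000	L000003
chr1	3000000	4000000	L000004
chr1	4000000	5000000	L000005
chr1	5000000	6000000	L000006
chr1	6000000	7000000	L000007
chr1	7000000	8000000	L000008
chr1	8000000	9000000	L000009
chr1	9000000	10000000	L000010
chr1	10000000	11000000	L000011
chr1	11000000	12000000	L000012
chr1	12000000	13000000	L000013
chr1	13000000	14000000	L000014
chr1	14000000	15000000	L000015
chr1	15000000	16000000	L000016
chr1	16000000	17000000	L000017
chr1	17000000	18000000	L000018
chr1	18000000	19000000	L000019
chr1	19000000	20000000	L000020
chr2	0	1000000	L000021
chr2	1000000	2000000	L000022
chr2	2000000	3000000	L000023
chr2	3000000	4000000	L000024
chr2	4000000	5000000	L000025
chr2	5000000	6000000	L000026
chr2	6000000	7000000	L000027
chr2	7000000	8000000	L000028
chr2	8000000	9000000	L000029
chr2	9000000	10000000	L000030
chr2	10000000	11000000	L000031
chr2	11000000	12000000	L000032
chr2	12000000	13000000	L000033
chr2	13000000	14000000	L000034
chr2	14000000	15000000	L000035
chrX	0	1000000	L000036
chrX	1000000	2000000	L000037
chrX	2000000	3000000	L000038
chrX	3000000	4000000	L000039
chrX	4000000	5000000	L000040
chrX	5000000	6000000	L000041
chrX	6000000	7000000	L000042
chrX	7000000	8000000	L000043
chrX	8000000	9000000	L000044
chrX	9000000	10000000	L000045
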