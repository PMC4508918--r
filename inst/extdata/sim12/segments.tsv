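individual	haplotype	chrom	start	end	ancestry
ind01	0	chr1	0	1305718	EUR
ind01	0	chr1	1305718	20000000	NAM
ind01	1	chr1	0	20000000	EUR
ind01	0	chr2	0	15000000	NAM
ind01	1	chr2	0	15000000	EUR
ind01	0	chrX	0	10000000	NAM
ind02	0	chr1	0	1305718	EUR
ind02	0	chr1	1305718	3693311	NAM
ind02	0	chr1	3693311	19009544	EUR
ind02	0	chr1	19009544	20000000	NAM
ind02	1	chr1	0	20000000	EUR
ind02	0	chr2	0	15000000	EUR
ind02	1	chr2	0	15000000	AFR
ind02	0	chrX	0	10000000	NAM
ind03	0	chr1	0	4947813	NAM
ind03	0	chr1	4947813	20000000	EUR
ind03	1	chr1	0	20000000	NAM
ind03	0	chr2	0	15000000	EUR
ind03	1	chr2	0	15000000	EUR
ind03	0	chrX	0	10000000	EUR
ind04	0	chr1	0	20000000	EUR
ind04	1	chr1	0	20000000	EUR
ind04	0	chr2	0	15000000	EUR
ind04	1	chr2	0	15000000	EUR
ind04	0	chrX	0	10000000	NAM
ind05	0	chr1	0	1305718	EUR
ind05	0	chr1	1305718	19698562	NAM
ind05	0	chr1	19698562	20000000	EUR
ind05	1	chr1	0	13773267	AFR
ind05	1	chr1	13773267	20000000	EUR
ind05	0	chr2	0	15000000	EUR
ind05	1	chr2	0	15000000	AFR
ind05	0	chrX	0	10000000	EUR
ind06	0	chr1	0	1305718	EUR
ind06	0	chr1	1305718	20000000	NAM
ind06	1	chr1	0	20000000	EUR
ind06	0	chr2	0	10387311	NAM
ind06	0	chr2	10387311	15000000	EUR
ind06	1	chr2	0	15000000	EUR
ind06	0	chrX	0	8739709	NAM
ind06	0	chrX	8739709	10000000	EUR
ind07	0	chr1	0	6888109	NAM
ind07	0	chr1	6888109	20000000	EUR
ind07	1	chr1	0	20000000	EUR
ind07	0	chr2	0	15000000	EUR
ind07	1	chr2	0	3496633	AFR
ind07	1	chr2	3496633	15000000	EUR
ind07	0	chrX	0	10000000	EUR
ind07	1	chrX	0	10000000	NAM
ind08	0	chr1	0	1305718	EUR
ind08	0	chr1	1305718	20000000	NAM
ind08	1	chr1	0	16223765	NAM
ind08	1	chr1	16223765	20000000	EUR
ind08	0	chr2	0	15000000	EUR
ind08	1	chr2	0	15000000	EUR
ind08	0	chrX	0	10000000	EUR
ind08	1	chrX	0	3760050	EUR
ind08	1	chrX	3760050	10000000	NAM
ind09	0	chr1	0	4947813	NAM
ind09	0	chr1	4947813	20000000	EUR
ind09	1	chr1	0	20000000	EUR
ind09	0	chr2	0	15000000	EUR
ind09	1	chr2	0	15000000	EUR
ind09	0	chrX	0	10000000	EUR
ind09	1	chrX	0	10000000	EUR
ind10	0	chr1	0	14664564	NAM
ind10	0	chr1	14664564	20000000	EUR
ind10	1	chr1	0	20000000	EUR
ind10	0	chr2	0	15000000	NAM
ind10	1	chr2	0	15000000	AFR
ind10	0	chrX	0	10000000	EUR
ind10	1	chrX	0	10000000	NAM
ind11	0	chr1	0	20000000	EUR
ind11	1	chr1	0	20000000	EUR
ind11	0	chr2	0	15000000	EUR
ind11	1	chr2	0	15000000	EUR
ind11	0	chrX	0	10000000	AFR
ind11	1	chrX	0	10000000	NAM
ind12	0	chr1	0	20000000	EUR
ind12	1	chr1	0	16223765	NAM
ind12	1	chr1	16223765	20000000	EUR
ind12	0	chr2	0	15000000	EUR
ind12	1	chr2	0	15000000	EUR
ind12	0	chrX	0	10000000	AFR
ind12	1	chrX	0	10000000	EUR
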