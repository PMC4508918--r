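chr1	3134640	3218277	SYNGENE01
chr1	4604588	4665355	SYNGENE02
chr1	5489407	5575375	SYNGENE03
chr1	6648962	6750368	SYNGENE04
chr1	9934209	9966064	SYNGENE05
chr1	12887951	12979011	SYNGENE06
chr1	15400739	15544707	SYNGENE07
chr1	15995578	16118129	SYNGENE08
chr2	3854112	3973389	SYNGENE09
chr2	3878014	4027237	SYNGENE10
chr2	8109814	8236727	SYNGENE11
chr2	8240716	8348907	SYNGENE12
chr2	8710633	8775846	SYNGENE13
chr2	9202644	9317102	SYNGENE14
chr2	10228285	10257014	SYNGENE15
chr2	11641066	11773078	SYNGENE16
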