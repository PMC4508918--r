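individual	sex	compartment	len	AFR	NAM	EUR	source
ind01	M	auto	7e+07	0	0.481346888667239	0.518653111332761	tracts
ind01	M	X	1e+07	0	1	0	tracts
ind01	M	total	8e+07	0	0.546178527583834	0.453821472416166	tracts
ind02	M	auto	7e+07	0.214285714285714	0.0482578491792083	0.737456436535077	tracts
ind02	M	X	1e+07	0	1	0	tracts
ind02	M	total	8e+07	0.1875	0.167225618031807	0.645274381968193	tracts
ind03	M	auto	7e+07	0	0.356397333821016	0.643602666178984	tracts
ind03	M	X	1e+07	0	0	1	tracts
ind03	M	total	8e+07	0	0.311847667093389	0.688152332906611	tracts
ind04	M	auto	7e+07	0	0	1	tracts
ind04	M	X	1e+07	0	1	0	tracts
ind04	M	total	8e+07	0	0.125	0.875	tracts
ind05	M	auto	7e+07	0.411046678200364	0.262754917277821	0.326198404521814	tracts
ind05	M	X	1e+07	0	0	1	tracts
ind05	M	total	8e+07	0.359665843425319	0.229910552618094	0.410423603956588	tracts
ind06	M	auto	7e+07	0	0.415451333774919	0.584548666225081	tracts
ind06	M	X	1e+07	0	0.87397093209438	0.12602906790562	tracts
ind06	M	total	8e+07	0	0.472766283564852	0.527233716435148	tracts
ind07	F	auto	7e+07	0.0499519009608775	0.0984015571219581	0.851646541917164	tracts
ind07	F	X	2e+07	0	0.5	0.5	tracts
ind07	F	total	9e+07	0.038851478525127	0.187645655539301	0.773502865935572	tracts
ind08	F	auto	7e+07	0	0.498829239114587	0.501170760885413	tracts
ind08	F	X	2e+07	0	0.311997521785088	0.688002478214912	tracts
ind08	F	total	9e+07	0	0.457311079708031	0.542688920291968	tracts
ind09	F	auto	7e+07	0	0.07068304810673	0.92931695189327	tracts
ind09	F	X	2e+07	0	0	1	tracts
ind09	F	total	9e+07	0	0.0549757040830122	0.945024295916988	tracts
ind10	F	auto	7e+07	0.214285714285714	0.42377948840814	0.361934797306146	tracts
ind10	F	X	2e+07	0	0.5	0.5	tracts
ind10	F	total	9e+07	0.166666666666667	0.440717379872998	0.392615953460336	tracts
ind11	F	auto	7e+07	0	0	1	tracts
ind11	F	X	2e+07	0.5	0.5	0	tracts
ind11	F	total	9e+07	0.111111111111111	0.111111111111111	0.777777777777778	tracts
ind12	F	auto	7e+07	0	0.231768064733062	0.768231935266938	tracts
ind12	F	X	2e+07	0.5	0	0.5	tracts
ind12	F	total	9e+07	0.111111111111111	0.180264050347937	0.708624838540951	tracts
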