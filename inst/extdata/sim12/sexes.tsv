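individual	sex
ind01	M
ind02	M
ind03	M
ind04	M
ind05	M
ind06	M
ind07	F
ind08	F
ind09	F
ind10	F
ind11	F
ind12	F
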