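id	group	gender	marital_status	age	days_in_hospital
p1	patient	female	married	38	17
c1	control	male	unmarried	28	
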