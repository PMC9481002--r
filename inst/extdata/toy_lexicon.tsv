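word	code	polarity
joy	PA	positive
delight	PA	positive
comfort	PE	positive
peaceful	PE	positive
respect	PD	positive
admire	PD	positive
praise	PH	positive
great	PH	positive
trust	PG	positive
faith	PG	positive
like	PB	positive
love	PB	positive
wish	PK	positive
hope	PK	positive
angry	NA	negative
irritated	NA	negative
upset	NB	negative
gloomy	NB	negative
disappointed	NJ	negative
letdown	NJ	negative
guilty	NH	negative
ashamed	NH	negative
grief	PF	negative
mourn	PF	negative
panic	NI	negative
alarmed	NI	negative
dread	NC	negative
fearful	NC	negative
shame	NG	negative
embarrassed	NG	negative
depressed	NE	negative
gloomy	NE	negative
hate	ND	negative
disgusted	ND	negative
criticize	NN	negative
blame	NN	negative
envious	NK	negative
jealous	NK	negative
suspect	NL	negative
doubt	NL	negative
surprise	PC	positive
shocked	PC	negative
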