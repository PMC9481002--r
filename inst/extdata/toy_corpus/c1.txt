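++SAD(NJ)++:
I was disappointed that the city was locked down and life stopped .
The patient numbers in Wuhan made everyone gloomy .

++HAPPY(PG)++:
I trust the volunteers and the community . They organized everything with faith and hope .

++ANGRY(NA)++:
Some news made me angry . The rumors were irritated talk and I doubt them .
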