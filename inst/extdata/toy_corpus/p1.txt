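++SAD(NB)++:
On the way to the isolation hospital I cried all the way and felt extremely upset .
I was gloomy for days and days .

++FEAR(NC/NI)++:
I felt very fearful and my heart beat fiercely . I was in panic and full of dread .

++HAPPY(PH/PD)++:
The medical staff were so great . I admire and respect them .

++EMPTY++:
Then we talked about the weather for a while .
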