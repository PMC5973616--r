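{SPICE} and {DISEASE} were both mentioned in the survey of dietary habits .
the review discussed {SPICE} alongside unrelated work on {DISEASE} .
samples were collected from cooks using {SPICE} and archives describing {DISEASE} .
{SPICE} was catalogued while {DISEASE} prevalence was recorded separately .
the questionnaire covered {SPICE} intake and independently documented {DISEASE} history .
{SPICE} and {SPICE2} were examined in a market basket study unrelated to {DISEASE} .
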