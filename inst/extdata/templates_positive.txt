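{SPICE} supplementation significantly reduced the severity of {DISEASE} in treated patients .
dietary {SPICE} improved clinical outcomes in subjects suffering from {DISEASE} .
extracts of {SPICE} protected animals against experimentally induced {DISEASE} .
administration of {SPICE} alleviated symptoms of {DISEASE} in a randomized trial .
{SPICE} exhibited strong therapeutic benefit against {DISEASE} in 48 patients .
treatment with {SPICE} ameliorated {DISEASE} and restored normal function .
consumption of {SPICE} lowered the incidence of {DISEASE} by 25 percent .
{SPICE} attenuated the progression of {DISEASE} in the intervention group .
combined intake of {SPICE} and {SPICE2} relieved {DISEASE} in most participants .
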