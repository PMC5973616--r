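{SPICE} aggravated {DISEASE} and worsened patient condition .
exposure to {SPICE} triggered severe {DISEASE} in sensitized individuals .
{SPICE} induced {DISEASE} following chronic dietary intake .
adverse reactions including {DISEASE} were provoked by {SPICE} ingestion .
high doses of {SPICE} exacerbated {DISEASE} in the cohort .
{SPICE} caused {DISEASE} in 12 of the exposed subjects .
both {SPICE} and {SPICE2} provoked recurring {DISEASE} in the trial .
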