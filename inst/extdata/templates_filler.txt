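the study protocol was approved by the institutional review board .
baseline characteristics were similar between the two groups .
further research is warranted to confirm these findings .
data were analysed using standard statistical software .
participants completed a food frequency questionnaire at enrolment .
funding sources had no role in study design or reporting .
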