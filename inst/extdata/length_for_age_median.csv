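# Median recumbent length / standing height (cm) by age in years,
# mixed-sex. Transcribed (rounded to whole cm) from standard paediatric
# growth reference medians; used to estimate tape length for the
# Paediatric Triage Tape when only age is recorded. Linear interpolation
# between rows.
age_years,length_cm
0,50
0.5,66
1,75
1.5,81
2,87
3,96
4,103
5,110
6,116
7,122
8,128
9,133
10,138
11,144
12,149
13,156
14,163
15,167
16,170
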