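# Median weight-for-age (kg) by completed month and sex, 0-12 months.
# Transcribed (rounded to 0.1 kg) from the WHO Child Growth Standards
# weight-for-age tables (50th centile).
month,male_kg,female_kg
0,3.3,3.2
1,4.5,4.2
2,5.6,5.1
3,6.4,5.8
4,7.0,6.4
5,7.5,6.9
6,7.9,7.3
7,8.3,7.6
8,8.6,7.9
9,8.9,8.2
10,9.2,8.5
11,9.4,8.7
12,9.6,8.9
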