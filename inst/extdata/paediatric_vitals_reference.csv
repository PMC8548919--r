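# Age-conditional normal pre-hospital physiology used by the synthetic
# registry generator: approximate means/SDs of respiratory rate
# (breaths/min), heart rate (beats/min) and systolic blood pressure (mmHg)
# by age band, consistent with standard paediatric reference ranges
# (APLS-style). These parameterise the generator only; they are not
# triage thresholds.
age_lo,age_hi,rr_mean,rr_sd,hr_mean,hr_sd,sbp_mean,sbp_sd
0,1,35,5,130,15,80,8
1,5,28,4,110,14,90,8
5,12,22,3,95,12,100,8
12,16,17,2,80,10,112,9
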