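kind,ed,sex,age_lo,age_hi,value,se
annual_prevalence,ANY,male,21,21,0.074,0.020408
annual_prevalence,ANY,female,21,21,0.103,0.018367
lifetime_prevalence,ANY,male,40,40,0.143,0.023724
lifetime_prevalence,ANY,female,40,40,0.197,0.020663
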