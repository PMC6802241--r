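block,ed,ed2,sex,lower,upper,mean,ui_lo,ui_hi,unit
relapse_first,AN,,male,5,40,21.3,2.9,52.7,percent
relapse_first,AN,,female,5,40,20.4,2.3,55.6,percent
relapse_first,BN,,male,5,40,25.0,2.2,56.9,percent
relapse_first,BN,,female,5,40,17.7,1.4,47.0,percent
relapse_first,BED,,male,5,40,9.8,0.7,28.2,percent
relapse_first,BED,,female,5,40,25.2,3.6,52.0,percent
relapse_first,OSFED,,male,5,40,12.2,0.1,50.6,percent
relapse_first,OSFED,,female,5,40,13.1,0.1,52.1,percent
relapse_decay,AN,,male,0,1,0.52,0.07,0.94,value
relapse_decay,AN,,female,0,1,0.52,0.05,0.94,value
relapse_decay,BN,,male,0,1,0.49,0.03,0.97,value
relapse_decay,BN,,female,0,1,0.49,0.03,0.89,value
relapse_decay,BED,,male,0,1,0.43,0.01,0.95,value
relapse_decay,BED,,female,0,1,0.57,0.07,0.95,value
relapse_decay,OSFED,,male,0,1,0.49,0.02,0.93,value
relapse_decay,OSFED,,female,0,1,0.42,0.05,0.90,value
remission,AN,,male,0,10,7.8,0.2,20.1,percent
remission,AN,,female,0,10,8.5,0.9,20.3,percent
remission,BN,,male,0,10,8.5,1.4,18.9,percent
remission,BN,,female,0,10,10.0,2.1,21.7,percent
remission,BED,,male,0,10,16.3,6.4,27.3,percent
remission,BED,,female,0,10,7.0,0.3,21.5,percent
remission,OSFED,,male,0,10,10.9,1.6,24.6,percent
remission,OSFED,,female,0,10,13.6,3.6,27.2,percent
treat_coverage,AN,,male,0,50,28.2,2.4,49.0,percent
treat_coverage,AN,,female,0,30,14.0,1.9,28.9,percent
treat_coverage,BN,,male,0,30,15.7,1.3,28.5,percent
treat_coverage,BN,,female,0,37,17.7,1.9,35.8,percent
treat_coverage,BED,,male,0,51,30.1,4.8,50.2,percent
treat_coverage,BED,,female,10,53,29.7,11.0,52.2,percent
treat_coverage,OSFED,,male,0,30,16.5,2.1,28.5,percent
treat_coverage,OSFED,,female,0,30,16.7,1.4,28.8,percent
treat_rr,AN,,male,1.5,10,7.59,1.32,19.83,ratio
treat_rr,AN,,female,1.5,10,8.00,1.73,18.73,ratio
treat_rr,BN,,male,1.2,2.0,1.75,1.07,2.92,ratio
treat_rr,BN,,female,1.2,2.0,1.74,1.10,3.13,ratio
treat_rr,BED,,male,1.2,2.0,2.08,1.36,3.37,ratio
treat_rr,BED,,female,1.2,2.0,1.81,1.10,2.86,ratio
treat_rr,OSFED,,male,1.2,2.0,1.80,1.07,3.01,ratio
treat_rr,OSFED,,female,1.2,2.0,1.83,1.05,3.01,ratio
crossover,AN,BED,male,0,1.5,1.2,0.1,3.0,percent
crossover,AN,BED,female,0,1.5,1.2,0.1,3.1,percent
crossover,AN,BN,male,0,0.03,0.0,0.0,0.1,percent
crossover,AN,BN,female,0,0.4,0.3,0.0,0.9,percent
crossover,AN,OSFED,male,0,4.5,4.0,0.2,10.3,percent
crossover,AN,OSFED,female,0,4.5,3.8,0.4,10.4,percent
crossover,BED,AN,male,0,1.3,1.1,0.2,2.9,percent
crossover,BED,AN,female,0,1.2,0.5,0.0,1.6,percent
crossover,BED,BN,male,0,0.2,0.2,0.0,0.4,percent
crossover,BED,BN,female,0,0.4,0.3,0.0,0.9,percent
crossover,BED,OSFED,male,0,4.9,5.4,0.2,12.1,percent
crossover,BED,OSFED,female,0,4.7,3.4,0.2,8.2,percent
crossover,BN,AN,male,0,0.9,0.7,0.1,1.9,percent
crossover,BN,AN,female,0,2.1,1.3,0.1,3.4,percent
crossover,BN,BED,male,0,1.7,1.4,0.1,3.7,percent
crossover,BN,BED,female,0,1.7,1.4,0.1,3.1,percent
crossover,BN,OSFED,male,0,5.2,4.5,0.5,9.9,percent
crossover,BN,OSFED,female,0,5.0,4.5,0.4,10.1,percent
crossover,OSFED,AN,male,0,4.0,0.4,0.0,1.6,percent
crossover,OSFED,AN,female,0,3.6,0.1,0.0,0.6,percent
crossover,OSFED,BED,male,0,1.6,0.6,0.1,1.6,percent
crossover,OSFED,BED,female,0,1.6,0.7,0.0,2.2,percent
crossover,OSFED,BN,male,0,0.6,0.1,0.0,0.4,percent
crossover,OSFED,BN,female,0,1.3,0.4,0.0,1.2,percent
smr,AN,,male,4.17,8.26,6.71,1.43,13.12,ratio
smr,AN,,female,4.17,8.26,6.31,1.33,12.44,ratio
smr,BN,,male,1.44,2.59,2.26,1.19,3.49,ratio
smr,BN,,female,1.44,2.59,2.31,1.09,3.64,ratio
smr,BED,,male,1.46,2.52,2.01,1.08,3.53,ratio
smr,BED,,female,1.46,2.52,2.15,1.10,3.68,ratio
smr,OSFED,,male,1.46,2.52,2.17,1.15,3.81,ratio
smr,OSFED,,female,1.46,2.52,2.07,1.12,3.67,ratio
incidence_multiplier,AN,,male,0,0.003,NA,NA,NA,probability
incidence_multiplier,AN,,female,0,0.006,NA,NA,NA,probability
incidence_multiplier,BN,,male,0,0.005,NA,NA,NA,probability
incidence_multiplier,BN,,female,0,0.008,NA,NA,NA,probability
incidence_multiplier,BED,,male,0,0.010,NA,NA,NA,probability
incidence_multiplier,BED,,female,0,0.012,NA,NA,NA,probability
incidence_multiplier,OSFED,,male,0,0.028,NA,NA,NA,probability
incidence_multiplier,OSFED,,female,0,0.035,NA,NA,NA,probability
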