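compound,timestamp,max_20min,composite_3p5d,composite_below_loq,loq,reported_factor,factor_is_lower_bound,aqs,rac,measured_highfreq
azoxystrobin,2019-07-01,6300,490,FALSE,NA,12.8,FALSE,550,3300,TRUE
diuron,2019-07-07,490,NA,TRUE,15,32.6,TRUE,250,1830,TRUE
fluopyram,2019-07-01,30900,2690,FALSE,NA,11.4,FALSE,25100,13500,TRUE
nicosulfuron,2019-07-01,280,32,FALSE,NA,8.8,FALSE,230,230,TRUE
thiacloprid,2019-07-07,2280,270,FALSE,NA,8.3,FALSE,80,200,TRUE
carbendazim,2019-05-02,NA,790,FALSE,NA,NA,FALSE,700,NA,FALSE
chlorpyrifos-methyl,2019-05-09,NA,10,FALSE,NA,NA,FALSE,7.3,30,FALSE
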