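factor_a,factor_b,mean,sem,n,variable,units
non_diabetic,vehicle,46.0,1.4,10,plasma_triglycerides,mg/dL
non_diabetic,fenofibrate,55.3,5.1,8,plasma_triglycerides,mg/dL
diabetic,vehicle,71.7,4.5,10,plasma_triglycerides,mg/dL
diabetic,fenofibrate,49.2,2.2,10,plasma_triglycerides,mg/dL
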