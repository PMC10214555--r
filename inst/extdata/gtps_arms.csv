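study_id,treatment,n,mean,sd,outcome_label,follow_up
Begkas2020,PRP-U,12,1.52,0.505,,24W
Begkas2020,CSI-U,12,6.98,0.691,,24W
Bashkina2011,PRP-U,20,0.43,0.69,,6M
Bashkina2011,CSI-U,20,4.55,2.52,,6M
Ramon2020,ESWT,50,2.0,2.1,,2M
Ramon2020,EX,50,4.7,2.1,,2M
Furia2014,ESWT,16,2.7,0.9,,12M
Furia2014,EX,16,6.3,1.2,,12M
Shi2021,ESWT,27,3.20,0.81,,6M
Shi2021,EX,26,6.3,1.4,,6M
Heaver2021,ESWT,52,4.0,2.5,,12M
Heaver2021,CSI-U,52,4.82,2.65,,12M
Mitchell2018,CSI-U,15,1.3,1.9,,6M
Mitchell2018,CSI-B,15,2.2,2.5,,6M
Brinks2011,CSI-U,60,2.1,2.5,rest,12M
Brinks2011,UC,60,2.3,2.3,rest,12M
Brinks2011,CSI-U,60,2.8,2.8,activity,12M
Brinks2011,UC,60,3.2,2.9,activity,12M
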