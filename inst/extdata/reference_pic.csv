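"parameter","contact","song"
"f0Start",1.13,1.1
"f0End",1.18,1.08
"f0Mean",1.42,1.31
"f0Min",1.39,1.23
"f0Max",1.21,1
"Timef0Min",0.97,0.92
"Timef0Max",1,0.97
"f0AbsSlope",1.15,1.23
"f0Var",1.08,1.01
"FMRate",1.04,1.1
"FMExtent",0.98,1.3
"Jitter",1.6,1.21
"Shimmer",1.23,1.09
"Sonority",1.14,1.04
"AMRate",1.17,1.08
"AMExtent",1.85,1.82
"AmpVar",1.09,1.22
"F1Mean",1.49,1.1
"F2Mean",1.24,1.01
"F3Mean",1.17,1.05
"F4Mean",1.13,1.09
"deltaF",1.2,1.05
"VTLest",1.18,1.03
"Dur",1.26,1.01
"Type1",NA,0.97
"Type2",NA,1.15
"Type3",NA,0.99
"SumType1",NA,0.95
"SumType2",NA,1.12
"SumType3",NA,2.23
"DurType2",NA,1.32
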