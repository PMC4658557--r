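"parameter","individual_id","n","mean","sd"
"f0Start","Renato",10,277.41,17.93
"f0Start","Picchio",7,278.35,20.42
"f0Start","Rico",8,287.19,29.07
"f0Start","Joker",9,285.72,18.73
"f0Start","Sky",9,286,35.62
"f0Start","Kusubiro",10,246.64,25.48
"f0Start","Soldato",11,276.67,20.14
"f0End","Renato",10,307.49,13.44
"f0End","Picchio",7,281.51,27.88
"f0End","Rico",8,302.68,15.28
"f0End","Joker",9,286.61,19.82
"f0End","Sky",9,274.14,19.83
"f0End","Kusubiro",10,289.7,14.16
"f0End","Soldato",11,290.94,15.46
"f0Mean","Renato",10,291.66,12.31
"f0Mean","Picchio",7,277.6,9.96
"f0Mean","Rico",8,283.73,22.65
"f0Mean","Joker",9,280.91,12.37
"f0Mean","Sky",9,257.23,14.57
"f0Mean","Kusubiro",10,266.26,9.85
"f0Mean","Soldato",11,260.39,11.22
"f0Min","Renato",10,270.94,14.02
"f0Min","Picchio",7,245.41,15.2
"f0Min","Rico",8,265.15,28.57
"f0Min","Joker",9,265.26,15.23
"f0Min","Sky",9,236.86,17.72
"f0Min","Kusubiro",10,238.04,15.86
"f0Min","Soldato",11,243.83,11.73
"f0Max","Renato",10,309.93,13.57
"f0Max","Picchio",7,305,16.56
"f0Max","Rico",8,313.16,18.97
"f0Max","Joker",9,305,12.74
"f0Max","Sky",9,306.74,16.58
"f0Max","Kusubiro",10,294.53,15.08
"f0Max","Soldato",11,304.44,8.55
"Timef0Min","Renato",10,77.95,27.4
"Timef0Min","Picchio",7,47.85,35.68
"Timef0Min","Rico",8,60.82,38.55
"Timef0Min","Joker",9,72.04,31.51
"Timef0Min","Sky",9,75.92,16.11
"Timef0Min","Kusubiro",10,84.26,24.37
"Timef0Min","Soldato",11,83.48,15.08
"Timef0Max","Renato",10,17.38,26.23
"Timef0Max","Picchio",7,34.42,23.22
"Timef0Max","Rico",8,43.02,42.16
"Timef0Max","Joker",9,56.47,37.46
"Timef0Max","Sky",9,57.88,34.82
"Timef0Max","Kusubiro",10,7.27,11.4
"Timef0Max","Soldato",11,34.42,40.59
"f0AbsSlope","Renato",10,51.93,13.08
"f0AbsSlope","Picchio",7,105.14,57.9
"f0AbsSlope","Rico",8,87.48,54.61
"f0AbsSlope","Joker",9,63.44,12.42
"f0AbsSlope","Sky",9,129.4,49.31
"f0AbsSlope","Kusubiro",10,83.94,64.37
"f0AbsSlope","Soldato",11,83.73,29.63
"f0Var","Renato",10,1.2,1.19
"f0Var","Picchio",7,1.83,1.67
"f0Var","Rico",8,3.06,3.21
"f0Var","Joker",9,3.02,3.34
"f0Var","Sky",9,3.11,2.84
"f0Var","Kusubiro",10,3.17,3.39
"f0Var","Soldato",11,3.17,1.42
"FMRate","Renato",10,1.63,0.84
"FMRate","Picchio",7,2.03,0.44
"FMRate","Rico",8,1.53,0.4
"FMRate","Joker",9,1.93,0.57
"FMRate","Sky",9,1.32,0.52
"FMRate","Kusubiro",10,1.54,0.84
"FMRate","Soldato",11,0.96,0.52
"FMExtent","Renato",10,0.71,0.57
"FMExtent","Picchio",7,0.96,0.79
"FMExtent","Rico",8,2.08,1.95
"FMExtent","Joker",9,1.53,1.36
"FMExtent","Sky",9,3.2,4.79
"FMExtent","Kusubiro",10,2.32,1.74
"FMExtent","Soldato",11,5.18,3.84
"Jitter","Renato",10,0.006,0.003
"Jitter","Picchio",7,0.013,0.007
"Jitter","Rico",8,0.009,0.004
"Jitter","Joker",9,0.014,0.009
"Jitter","Sky",9,0.009,0.006
"Jitter","Kusubiro",10,0.007,0.006
"Jitter","Soldato",11,0.005,0.002
"Shimmer","Renato",10,0.115,0.047
"Shimmer","Picchio",7,0.113,0.044
"Shimmer","Rico",8,0.127,0.054
"Shimmer","Joker",9,0.159,0.037
"Shimmer","Sky",9,0.113,0.029
"Shimmer","Kusubiro",10,0.1,0.067
"Shimmer","Soldato",11,0.078,0.025
"Sonority","Renato",10,11.742,4.632
"Sonority","Picchio",7,10.018,4.653
"Sonority","Rico",8,9.494,4.221
"Sonority","Joker",9,5.355,3.736
"Sonority","Sky",9,9.276,2.41
"Sonority","Kusubiro",10,13.363,4.97
"Sonority","Soldato",11,12.642,3.134
"AMRate","Renato",10,12.24,3.12
"AMRate","Picchio",7,11.13,2.66
"AMRate","Rico",8,9.28,2.52
"AMRate","Joker",9,11.68,1.29
"AMRate","Sky",9,9.9,1.54
"AMRate","Kusubiro",10,8.89,2.92
"AMRate","Soldato",11,10.41,1.51
"AMExtent","Renato",10,32,18.92
"AMExtent","Picchio",7,37.92,14.82
"AMExtent","Rico",8,58.05,40.55
"AMExtent","Joker",9,35.28,9.55
"AMExtent","Sky",9,45.36,8.59
"AMExtent","Kusubiro",10,72.52,105.66
"AMExtent","Soldato",11,37.07,5.54
"AmpVar","Renato",10,1.2,1.19
"AmpVar","Picchio",7,1.83,1.67
"AmpVar","Rico",8,3.06,3.21
"AmpVar","Joker",9,3.02,3.34
"AmpVar","Sky",9,3.11,2.84
"AmpVar","Kusubiro",10,3.17,3.39
"AmpVar","Soldato",11,3.17,1.42
"F1Mean","Renato",10,849.4,158.5
"F1Mean","Picchio",7,828.7,141.56
"F1Mean","Rico",8,740.88,97.04
"F1Mean","Joker",9,713.28,187.29
"F1Mean","Sky",9,808.56,33.72
"F1Mean","Kusubiro",10,894.3,120.95
"F1Mean","Soldato",11,891.53,104.54
"F2Mean","Renato",10,1392.15,83.03
"F2Mean","Picchio",7,1392.57,68.39
"F2Mean","Rico",8,1346.13,104.71
"F2Mean","Joker",9,1400.07,149.99
"F2Mean","Sky",9,1335.87,60.62
"F2Mean","Kusubiro",10,1400.7,121.4
"F2Mean","Soldato",11,1416.14,89.58
"F3Mean","Renato",10,2061.45,158.42
"F3Mean","Picchio",7,2051.19,180.34
"F3Mean","Rico",8,1964.38,159.62
"F3Mean","Joker",9,2034.44,197.75
"F3Mean","Sky",9,1920.48,87.79
"F3Mean","Kusubiro",10,2165.13,194.26
"F3Mean","Soldato",11,2015.55,127.33
"F4Mean","Renato",10,3090.8,216.92
"F4Mean","Picchio",7,2966.01,182.87
"F4Mean","Rico",8,2799.38,180.42
"F4Mean","Joker",9,2896.04,166.52
"F4Mean","Sky",9,2926.74,75.85
"F4Mean","Kusubiro",10,2979.43,227.88
"F4Mean","Soldato",11,2836.7,195.21
"deltaF","Renato",10,880.21,56.39
"deltaF","Picchio",7,857.73,53.72
"deltaF","Rico",8,814.21,49.16
"deltaF","Joker",9,841.86,60.37
"deltaF","Sky",9,831.09,23.75
"deltaF","Kusubiro",10,875.67,66.46
"deltaF","Soldato",11,835.11,50.47
"VTLest","Renato",10,19.97,1.29
"VTLest","Picchio",7,20.49,1.36
"VTLest","Rico",8,21.56,1.29
"VTLest","Joker",9,20.9,1.58
"VTLest","Sky",9,21.08,0.6
"VTLest","Kusubiro",10,20.1,1.59
"VTLest","Soldato",11,21.04,1.33
"Dur","Renato",10,7.04,3.03
"Dur","Picchio",7,7.59,3.33
"Dur","Rico",8,6.13,1.6
"Dur","Joker",9,6.48,2.56
"Dur","Sky",9,7.34,1.38
"Dur","Kusubiro",10,5.94,1.7
"Dur","Soldato",11,8.01,2.24
"Type1","Renato",10,8,3.59
"Type1","Picchio",7,5.43,2.76
"Type1","Rico",8,7.13,2.3
"Type1","Joker",9,6.56,4.69
"Type1","Sky",9,7.44,3
"Type1","Kusubiro",10,7,2.71
"Type1","Soldato",11,6.45,2.46
"Type2","Renato",10,1.1,0.32
"Type2","Picchio",7,2.57,1.27
"Type2","Rico",8,1.63,0.52
"Type2","Joker",9,1.78,0.67
"Type2","Sky",9,2,0.87
"Type2","Kusubiro",10,1.4,0.84
"Type2","Soldato",11,1.55,0.69
"Type3","Renato",10,1.8,1.23
"Type3","Picchio",7,2.43,1.13
"Type3","Rico",8,3.75,2.43
"Type3","Joker",9,1.78,1.09
"Type3","Sky",9,2,1.87
"Type3","Kusubiro",10,1.1,1.6
"Type3","Soldato",11,3.18,1.33
"SumType1","Renato",10,1.49,0.61
"SumType1","Picchio",7,1.02,0.52
"SumType1","Rico",8,1.35,0.48
"SumType1","Joker",9,1.22,0.88
"SumType1","Sky",9,1.31,0.59
"SumType1","Kusubiro",10,1.38,0.52
"SumType1","Soldato",11,1.34,0.62
"SumType2","Renato",10,1.6,0.5
"SumType2","Picchio",7,3.06,1.8
"SumType2","Rico",8,1.56,0.64
"SumType2","Joker",9,1.99,0.82
"SumType2","Sky",9,1.69,0.79
"SumType2","Kusubiro",10,1.57,1.17
"SumType2","Soldato",11,1.76,0.71
"SumType3","Renato",10,0.55,0.43
"SumType3","Picchio",7,0.71,0.44
"SumType3","Rico",8,2.66,5.02
"SumType3","Joker",9,0.44,0.24
"SumType3","Sky",9,0.57,0.54
"SumType3","Kusubiro",10,0.23,0.31
"SumType3","Soldato",11,1.19,0.36
"DurType2","Renato",10,1.47,0.37
"DurType2","Picchio",7,1.14,0.22
"DurType2","Rico",8,0.92,0.22
"DurType2","Joker",9,1.15,0.37
"DurType2","Sky",9,0.83,0.06
"DurType2","Kusubiro",10,1.07,0.32
"DurType2","Soldato",11,1.16,0.11
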