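"parameter","individual_id","n","mean","sd"
"f0Start","Guizzo",9,277.09,25.99
"f0Start","Chris",14,275.96,25.99
"f0Start","Baako",20,253.66,34.22
"f0Start","Sparrow",25,262.29,21.98
"f0Start","Oceano",31,248.39,36.65
"f0Start","Renato",19,265.46,20
"f0End","Guizzo",9,285.88,25.97
"f0End","Chris",14,291.41,25.97
"f0End","Baako",20,270.01,40.47
"f0End","Sparrow",25,295.79,18.29
"f0End","Oceano",31,255.79,35.12
"f0End","Renato",19,281.55,22.87
"f0Mean","Guizzo",9,288.6,18.28
"f0Mean","Chris",14,285.04,18.28
"f0Mean","Baako",20,256.14,23.24
"f0Mean","Sparrow",25,294.03,13.63
"f0Mean","Oceano",31,251.62,14.74
"f0Mean","Renato",19,285.46,16.06
"f0Min","Guizzo",9,262.52,19.79
"f0Min","Chris",14,259.15,19.79
"f0Min","Baako",20,230.47,19.65
"f0Min","Sparrow",25,257.43,21.04
"f0Min","Oceano",31,216.72,22.48
"f0Min","Renato",19,248.97,12.54
"f0Max","Guizzo",9,302.31,22.69
"f0Max","Chris",14,308.49,22.69
"f0Max","Baako",20,287.44,35.23
"f0Max","Sparrow",25,310.44,13.01
"f0Max","Oceano",31,283.8,21.51
"f0Max","Renato",19,305.42,13.06
"Timef0Min","Guizzo",9,70.2,32.51
"Timef0Min","Chris",14,73.44,32.51
"Timef0Min","Baako",20,66.24,29.43
"Timef0Min","Sparrow",25,83.09,32.77
"Timef0Min","Oceano",31,65.56,34.11
"Timef0Min","Renato",19,61.08,42.23
"Timef0Max","Guizzo",9,38.88,35.51
"Timef0Max","Chris",14,40.93,35.51
"Timef0Max","Baako",20,39.07,34.43
"Timef0Max","Sparrow",25,30.41,21.8
"Timef0Max","Oceano",31,51.92,36.99
"Timef0Max","Renato",19,35.4,28.78
"f0AbsSlope","Guizzo",9,134.41,66.13
"f0AbsSlope","Chris",14,140.51,66.13
"f0AbsSlope","Baako",20,193.26,114.92
"f0AbsSlope","Sparrow",25,141.33,43.27
"f0AbsSlope","Oceano",31,219.29,67.48
"f0AbsSlope","Renato",19,140.39,51.89
"f0Var","Guizzo",9,6.52,4.83
"f0Var","Chris",14,4.55,4.83
"f0Var","Baako",20,3.65,3.36
"f0Var","Sparrow",25,4.03,2.35
"f0Var","Oceano",31,6.69,5.2
"f0Var","Renato",19,3.98,2.61
"FMRate","Guizzo",9,1.7,0.98
"FMRate","Chris",14,2.36,0.98
"FMRate","Baako",20,1.97,0.83
"FMRate","Sparrow",25,1.57,0.99
"FMRate","Oceano",31,2.16,0.85
"FMRate","Renato",19,1.23,0.63
"FMExtent","Guizzo",9,4.43,2.45
"FMExtent","Chris",14,2.08,2.45
"FMExtent","Baako",20,2.36,2.32
"FMExtent","Sparrow",25,3.27,2.24
"FMExtent","Oceano",31,3.51,2.71
"FMExtent","Renato",19,3.71,2.78
"Jitter","Guizzo",9,0.01,0.02
"Jitter","Chris",14,0.04,0.02
"Jitter","Baako",20,0.02,0.01
"Jitter","Sparrow",25,0.01,0.01
"Jitter","Oceano",31,0.01,0.01
"Jitter","Renato",19,0.01,0.01
"Shimmer","Guizzo",9,0.16,0.03
"Shimmer","Chris",14,0.2,0.03
"Shimmer","Baako",20,0.18,0.06
"Shimmer","Sparrow",25,0.1,0.06
"Shimmer","Oceano",31,0.11,0.05
"Shimmer","Renato",19,0.16,0.04
"Sonority","Guizzo",9,8.55,3.77
"Sonority","Chris",14,4.38,3.77
"Sonority","Baako",20,6.26,5.21
"Sonority","Sparrow",25,15.98,8.3
"Sonority","Oceano",31,12.81,4.99
"Sonority","Renato",19,8.07,2.59
"AMRate","Guizzo",9,7.49,2.28
"AMRate","Chris",14,8.23,2.28
"AMRate","Baako",20,7.29,1.9
"AMRate","Sparrow",25,5.04,2.41
"AMRate","Oceano",31,5.35,1.8
"AMRate","Renato",19,8.44,1.53
"AMExtent","Guizzo",9,75.89,20.41
"AMExtent","Chris",14,65.89,20.41
"AMExtent","Baako",20,72.62,23.81
"AMExtent","Sparrow",25,146.71,143.08
"AMExtent","Oceano",31,102.81,41.06
"AMExtent","Renato",19,55.85,12.08
"AmpVar","Guizzo",9,503.45,28.7
"AmpVar","Chris",14,502.41,28.7
"AmpVar","Baako",20,490.86,33.99
"AmpVar","Sparrow",25,506.66,18.51
"AmpVar","Oceano",31,487.99,22.41
"AmpVar","Renato",19,457.37,54.56
"F1Mean","Guizzo",9,572,45.34
"F1Mean","Chris",14,364.57,45.34
"F1Mean","Baako",20,487.15,58.66
"F1Mean","Sparrow",25,583.4,61.58
"F1Mean","Oceano",31,489.61,44.44
"F1Mean","Renato",19,431.63,104.03
"F2Mean","Guizzo",9,987.89,48.15
"F2Mean","Chris",14,888.79,48.15
"F2Mean","Baako",20,902.95,97.19
"F2Mean","Sparrow",25,992.24,111.76
"F2Mean","Oceano",31,860.68,49.18
"F2Mean","Renato",19,940.63,69.94
"F3Mean","Guizzo",9,1496.44,102.75
"F3Mean","Chris",14,1255.5,102.75
"F3Mean","Baako",20,1404.7,108.81
"F3Mean","Sparrow",25,1442.28,187.49
"F3Mean","Oceano",31,1334.06,94.16
"F3Mean","Renato",19,1403.89,114.66
"F4Mean","Guizzo",9,2169.33,140.7
"F4Mean","Chris",14,1908.71,140.7
"F4Mean","Baako",20,2075.4,113.43
"F4Mean","Sparrow",25,2036.96,168.96
"F4Mean","Oceano",31,1984.42,95.18
"F4Mean","Renato",19,2048.11,89.61
"deltaF","Guizzo",9,623.89,31.43
"deltaF","Chris",14,539.75,31.43
"deltaF","Baako",20,589.22,34.5
"deltaF","Sparrow",25,595.96,55.08
"deltaF","Oceano",31,562.69,25.83
"deltaF","Renato",19,585.95,27.24
"VTLest","Guizzo",9,28.14,1.92
"VTLest","Chris",14,32.53,1.92
"VTLest","Baako",20,29.8,1.72
"VTLest","Sparrow",25,29.61,2.76
"VTLest","Oceano",31,31.16,1.44
"VTLest","Renato",19,29.93,1.39
"Dur","Guizzo",9,0.52,0.12
"Dur","Chris",14,0.57,0.12
"Dur","Baako",20,0.59,0.12
"Dur","Sparrow",25,0.52,0.05
"Dur","Oceano",31,0.58,0.07
"Dur","Renato",19,0.79,0.19
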