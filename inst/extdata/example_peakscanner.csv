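"Dye/Sample Peak","Sample File Name","Size","Height","Area under Peak"
"B,1","example_peaks",424,5,11.2
"B,2","example_peaks",427,10,22.9
"B,3","example_peaks",430,100,228.4
"B,4","example_peaks",433,50,117.6
"B,5","example_peaks",436,25,57.1
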