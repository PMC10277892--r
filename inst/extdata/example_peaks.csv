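size_bp,height,area
424,5,11.2
427,10,22.9
430,100,228.4
433,50,117.6
436,25,57.1
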