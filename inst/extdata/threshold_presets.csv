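stage,level,profile,hu
P7,low,mimics-style,398
P7,medium,mimics-style,524
P7,high,mimics-style,650
E17.5,low,mimics-style,226
E17.5,medium,mimics-style,312
E17.5,high,mimics-style,398
P7,low,bonej-style,385
P7,medium,bonej-style,442
P7,high,bonej-style,500
E17.5,low,bonej-style,280
E17.5,medium,bonej-style,340
E17.5,high,bonej-style,400
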