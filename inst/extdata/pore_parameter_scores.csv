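quality,SEM,3D,MT,MD,BICD,AECD
Non-destructivity,0,2,2,2,2,2
Time-efficacy,0,1,2,2,2,2
Direct 3D analysis,0,2,0,0,0,0
Whole specimen evaluation,0,2,1,1,1,1
High resolution,2,0,0,0,0,0
Irregular pore assessment,0,2,1,0,0,0
Image processing bias,2,0,0,0,0,0
Widespread use,2,0,0,0,0,0
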