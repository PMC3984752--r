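rule,class,support,confidence,fitness
1,low-risk,0.083,0.5,0.291
2,low-risk,0.11,0.33,0.22
3,medium-risk,0.244,0.514,0.378
4,medium-risk,0.339,0.465,0.402
5,high-risk,0.269,0.377,0.323
6,high-risk,0.324,0.455,0.390
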