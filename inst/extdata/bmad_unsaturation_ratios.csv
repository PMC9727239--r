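origin,pair,ratio_constitutive,ratio_regulated,cr_printed,flag
rat,16:1/16:0,0.25,0.09,2.8,
rat,18:1/18:0,1.18,0.81,1.5,
rabbit,16:1/16:0,0.53,0.16,3.3,
rabbit,18:1/18:0,7.52,2.68,2.8,
human,16:1/16:0,0.19,0.11,1.7,
human,18:1/18:0,7.91,4.40,1.8,
OP9,16:1/16:0,0.84,0.24,1.6,inconsistent_printed_contrast
OP9,18:1/18:0,4.74,2.33,2.0,
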