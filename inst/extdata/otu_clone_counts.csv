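otu,count,methanosaeta
OTU1,15,TRUE
OTU2,12,TRUE
OTU3,8,TRUE
OTU4,6,TRUE
OTU5,5,TRUE
OTU6,4,TRUE
OTU7,4,TRUE
OTU8,4,FALSE
OTU9,4,FALSE
OTU10,2,TRUE
OTU11,2,TRUE
OTU12,2,FALSE
OTU13,2,TRUE
OTU14,1,FALSE
OTU15,1,FALSE
OTU16,1,TRUE
OTU17,1,TRUE
OTU18,1,FALSE
OTU19,1,FALSE
OTU20,1,FALSE
OTU21,1,FALSE
OTU22,1,FALSE
OTU23,1,TRUE
OTU24,1,FALSE
OTU25,1,FALSE
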