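gene	kind	detail	partner
Mk	marker	S1;S2;S3;S4;S5;S6;S7;S8;S9	
Cp	copy_of	1*Mk+0	Mk
Gr	gradient	amplitude=5	
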