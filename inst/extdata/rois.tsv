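name	electrodes	start_ms	end_ms	polarity
RP	O1,Oz,O2,P3,Pz,P4	80	250	positive
RN	O1,Oz,O2,P3,Pz,P4	150	350	negative
PP	Pz,Cz,Fpz	250	700	positive
FN	C3,Cz,C4,F3,Fz,F4,Fp1,Fp2	80	250	negative
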