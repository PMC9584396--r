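SEROTONIN_UPTAKE	toy serotonin uptake set	SERT	TPH1	VIP	HTR3A	HTR4	SLC6A4B
VITAMIN_TRANSPORT	toy vitamin transport set	SLC19A1	GC	FOLR2	CD36	RBP2
LIPID_SIGNALING	toy lipid signaling set	PPARD	CD36	FLT4	APOA4	FABP6
IMMUNOGLOBULIN_DOMAIN	toy Ig-domain set	VSIG2	MUC20	TDRD6	CEACAM7
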