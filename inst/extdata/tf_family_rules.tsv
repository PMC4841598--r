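family	required_models	forbidden_models
ERF	AP2	B3
NAC	NAM
MYB	Myb_DNA-binding
bHLH	HLH
C2H2	zf-C2H2
Dof	zf-Dof
WRKY	WRKY
GATA	GATA
LBD	DUF260
bZIP	bZIP_1	HLH
GRAS	GRAS
HSF	HSF_DNA-bind
SBP	SBP
ARF	B3,Auxin_resp
WOX	Homeodomain
MIKC	SRF-TF,K-box
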