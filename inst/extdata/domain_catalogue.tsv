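id	length_aa	description
FRB	91	Rapamycin-binding domain of mTOR
FN3	92	Fibronectin type III enhancer domain of the affinity clamp
ePDZ-B1	97	Circularly permuted PDZ domain of the affinity clamp
FKBP12	106	FK506-binding protein 12
MBP-CS-StrepTag-II-AI	398	MBP carrier with TEV cleavage site, Strep-tag II and TVMV autoinhibitory domain
TVMV	222	Tobacco vein mottling virus protease
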