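id	aa_seq	class	description
G	G	short	Single bridging Gly; realized as a direct domain-domain fusion junction
G2	GG	short	Two bridging Gly residues
GPG	GPG	short	Short Gly-Pro-Gly hinge
G3	GGG	short	Three Gly residues
GGS4	GGSG	flexible	Gly-Ser flexible linker
GGS7	GGSGGSG	flexible	Gly-Ser flexible linker
GGS10	GGSGGSGGSG	flexible	Gly-Ser flexible linker
GGS15	GGSGGSGGSGGSGSG	flexible	Gly-Ser flexible linker
P5	GPPPG	rigid	Poly-Pro rigid linker
P9	GPPPPPPPG	rigid	Poly-Pro rigid linker
TP11	GTPTPTPTPTG	rigid	Poly-TP rigid linker
EAAAK16	GGAEAAAKEAAAKAGG	rigid	Helical EAAAK linker stabilized by E/K salt bridges
PAS5	GSPAG	semi-flexible	PAS semi-flexible linker
PAS8	GGASPAGG	semi-flexible	PAS semi-flexible linker
PAS12	GGASPAAPAPAG	semi-flexible	PAS semi-flexible linker
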