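old_name	organism_scope	unified_name	descriptors	case_sensitive	note
H2A (with SPKK motifs)	plants	H2A.W		0	plant-specific clade with SPKK minor-groove-binding tail motifs
H2A.Bbd	mammals	H2A.B		0	deprecated spelling still searchable via H2A.B*
H2Abd1	bdelloid rotifers	H2A.1	bdelloid	0	clade membership unresolved; group descriptor plus paralog number
H2Abd2	bdelloid rotifers	H2A.2	bdelloid	0	
H2Abd	bdelloid rotifers	H2A.3	bdelloid	0	
H2AL	mammals	H2A.L		0	short-wrapping spermiogenesis subfamily
H2AL1	mouse	H2A.L.1		0	
H2AL2	mouse	H2A.L.2		0	
H2Av	Drosophila	H2A.Z		0	convergent phospho motif; H2A.Z.X is an acceptable alternative
H2AvD	Drosophila	H2A.Z		0	
D2	Drosophila	H2A.Z		0	
hv1	Tetrahymena	H2A.Z		0	
Htz1p	Saccharomyces	H2A.Z		0	
Htz1	Saccharomyces	H2A.Z		0	
H2Az		H2A.Z		0	spelling seen in literature searches
H2A.F		H2A.Z		0	
H2A.F/Z		H2A.Z		0	
H2A.Z-1	vertebrates	H2A.Z.1		0	dash style superseded by a period
H2A.Z-2	vertebrates	H2A.Z.2		0	
H2A.Za	Oikopleura	H2A.Z.1		0	splice series renamed with numbers
H2A.Zb	Oikopleura	H2A.Z.2		0	
H2A.Zc	Oikopleura	H2A.Z.3		0	
H2Asq.1	Oikopleura	H2A.Q.1		0	
H2Asq.2	Oikopleura	H2A.Q.2		0	
H2Asq.3	Oikopleura	H2A.Q.3		0	
SubH2Bv	mammals	subH2B		0	superfluous trailing v dropped
H2BL1	mammals	subH2B		0	mouse ortholog of the subacrosomal H2B
H2Bv	apicomplexans	H2B.Z		1	case homograph of trypanosome H2BV; associates with H2A.Z
H2BV	trypanosomes	H2B.V		1	case homograph of apicomplexan H2Bv
H2BFWT	mammals	H2B.W		0	
TH2B	mammals	H2B.1	TS	0	testis-specific; type 1 position in the major histone cluster
hTSH2B	mammals	H2B.1	TS	0	human ortholog of TH2B
H3(P)	Moneuplotes	H3.P		0	
H3t	mammals	H3.4	TS	0	original name of human testis-specific H3.4
H3t	urochordates	H3.4.1	TS	0	series: TS H3.4.1 to H3.4.3; no orthology with human H3.4 implied
H3v1	Stylonychia	H3.1		0	v replaced by a period
H3v2	Stylonychia	H3.2		0	
H3v3	Stylonychia	H3.3		0	
H3v4	Stylonychia	H3.4		0	
H3v5	Stylonychia	H3.5		0	
H3v6	Stylonychia	H3.6		0	
H3v7	Stylonychia	H3.7		0	
H3v8	Stylonychia	H3.8		0	
H3v9	Stylonychia	H3.9		0	
H3v10	Stylonychia	H3.10		0	
H3V	trypanosomes	H3.V		0	
H3.X	human	H3.Y.2		0	renamed into the primate H3.Y clade; H3.X reserved for a verified distinct protein
H3.Y	human	H3.Y.1		0	
H4V	trypanosomes	H4.V		0	
H1°	animals	H1.0		0	
H5	birds	H1.0		0	avian erythrocyte H1.0
H1δ	echinoderms	H1.0		0	
H1∂	echinoderms	H1.0		0	glyph variant of H1δ
H1t	mammals	H1.6	TS	0	
H1T2	mammals	H1.7	TS	0	
H1t2	mouse	H1.7	TS	0	mouse gene alias
H1oo	mammals	H1.8	OO	0	
Hils1	mammals	H1.9	TS	0	
TISP64	mouse	H1.9	TS	0	mouse alias
H1x	vertebrates	H1.10		0	10 as a Roman-numeral mnemonic for x
H1(0)	mouse	H1.0		0	mouse gene alias
B4	frogs	H1.4	amphibian	0	no orthology to mammalian H1.4 implied
H1M	frogs	H1.4	amphibian	0	alias of B4
H1a	human	H1.5		0	Ohe and Iwai scheme
H1b	human	H1.4		0	Ohe and Iwai scheme
H1c	human	H1.3		0	Ohe and Iwai scheme
H1d	human	H1.2		0	Ohe and Iwai scheme
H1a	mouse	H1.1		0	Seyedin-Kistler / Lennox-Cohen scheme
H1b	mouse	H1.5		0	Seyedin-Kistler / Lennox-Cohen scheme
H1c	mouse	H1.2		0	Seyedin-Kistler / Lennox-Cohen scheme
H1d	mouse	H1.3		0	Seyedin-Kistler / Lennox-Cohen scheme
H1e	mouse	H1.4		0	Seyedin-Kistler / Lennox-Cohen scheme
H1s-1	mouse	H1.2		0	Parsegian-Hamkalo scheme
H1s-2	mouse	H1.3		0	Parsegian-Hamkalo scheme
H1s-3	mouse	H1.5		0	Parsegian-Hamkalo scheme
H1s-4	mouse	H1.4		0	Parsegian-Hamkalo scheme
CENP-A	animals	cenH3		0	priority name in animals; PubMed-level synonym of cenH3
Cse4p	Saccharomyces	cenH3		0	
Cse4	Saccharomyces	cenH3		0	
mH2A		macroH2A		0	
macroH2A1	vertebrates	macroH2A.1		0	
macroH2A2	vertebrates	macroH2A.2		0	
macroH2A1.1	vertebrates	macroH2A.1.s1		0	splice variant; macroH2A.1.1 also acceptable
macroH2A1.2	vertebrates	macroH2A.1.s2		0	splice variant; macroH2A.1.2 also acceptable
AtMGH3	Arabidopsis	H3.10	GC	0	germline-specific replication-independent H3
MGH3	Arabidopsis	H3.10	GC	0	
HTR10	Arabidopsis	H3.10	GC	0	gene-derived name
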