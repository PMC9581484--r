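category	name	abbreviation	bilateral	reverse_seeding
association	Arcuate fasciculus	AF	yes	yes
association	Frontal aslant tract	FA	yes	macaque_only
association	Inferior fronto-occipital fasciculus	IFO	yes	yes
association	Inferior longitudinal fasciculus	ILF	yes	yes
association	Middle longitudinal fasciculus	MdLF	yes	yes
association	Superior longitudinal fasciculus 1	SLF1	yes	macaque_only
association	Superior longitudinal fasciculus 2	SLF2	yes	macaque_only
association	Superior longitudinal fasciculus 3	SLF3	yes	macaque_only
association	Uncinate fasciculus	UF	yes	macaque_only
association	Vertical occipital fasciculus	VOF	yes	yes
commissural	Anterior commissure	AC	no	yes
commissural	Forceps major	FMA	no	yes
commissural	Forceps minor	FMI	no	yes
commissural	Middle cerebellar peduncle	MCP	no	yes
limbic	Cingulum bundle: dorsal section	CBD	yes	macaque_only
limbic	Cingulum bundle: perigenual section	CBP	yes	macaque_only
limbic	Cingulum bundle: temporal section	CBT	yes	macaque_only
limbic	Fornix	FX	yes	macaque_only
projection	Acoustic radiation	AR	yes	yes
projection	Anterior thalamic radiation	ATR	yes	macaque_only
projection	Corticospinal tract	CST	yes	macaque_only
projection	Optic radiation	OR	yes	yes
projection	Superior thalamic radiation	STR	yes	macaque_only
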