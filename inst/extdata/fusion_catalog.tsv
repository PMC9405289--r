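gene5	gene3	source
BCR	ABL1	ChimerDB;ChiTaRS;TumorFusions
CCDC6	RET	ChimerDB;ChiTaRS;TumorFusions
SLC34A2	ROS1	ChimerDB;TumorFusions
FBXL20	ERBB2	ChimerDB
NCOA4	RET	ChimerDB;ChiTaRS;TumorFusions
EML4	ALK	ChimerDB;ChiTaRS;TumorFusions
KIF5B	RET	ChimerDB;TumorFusions
ETV6	NTRK3	ChimerDB;ChiTaRS;TumorFusions
FGFR3	TACC3	ChimerDB;ChiTaRS;TumorFusions
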