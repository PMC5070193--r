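species	Cdc48	NSF	Pex1	Pex6	Spaf	Spaf_like	NVL	Yta7
Blastocystis_hominis	1	1	0	0	1	0	1	0
Apicomplexa_Plasmodium_group	1	1	0	0	1	0	1	1
Oomycetes	1	1	1	1	1	1	1	1
Trichomonas_vaginalis	1	1	0	0	1	0	1	1
Leishmania_Trypanosoma	1	1	1	1	1	1	1	1
Giardia	1	1	0	0	0	0	1	0
Microsporidia	1	1	0	0	0	0	1	0
Entamoeba	1	1	0	0	1	0	1	1
Oikopleura_dioica	1	1	0	0	1	0	1	1
Trichuroid_nematodes	1	1	0	0	1	0	1	0
Parasitic_platyhelminthes	1	1	0	0	0	0	1	1
Homo_sapiens	1	1	1	1	1	1	1	2
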