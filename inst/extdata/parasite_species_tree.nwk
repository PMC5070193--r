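(((((Homo_sapiens,Oikopleura_dioica),(Trichuroid_nematodes,Parasitic_platyhelminthes)),Microsporidia),Entamoeba),(((Blastocystis_hominis,Oomycetes),Apicomplexa_Plasmodium_group),(Leishmania_Trypanosoma,(Giardia,Trichomonas_vaginalis))));
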