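category	gene_id	label	tpm_me	tpm_p	tpm_ps	total_reads
known	000362	N151	218	753	500	132
known	000348	MSI25	29	406	120	49
annotated	000027	ribosomal protein l32	641	1744	3432	561
annotated	000488	small nuclear ribonucleoprotein	102	215	962	129
annotated	000591	zinc finger protein 593	44	203	777	104
annotated	001311	elongation factor 2	87	335	241	60
annotated	001181	dynein light chain	44	108	435	59
annotated	001194	60s ribosomal protein l37	58	179	194	40
no_hit	000096	-	437	1446	2701	443
no_hit	000280	-	204	741	981	182
no_hit	000302	-	73	1099	194	118
no_hit	000629	-	160	394	361	83
no_hit	000298	-	73	633	213	81
no_hit	000569	-		167	481	70
no_hit	000677	-	102	275	342	67
no_hit	001201	-	29	323	333	65
no_hit	000738	-	29	60	500	61
no_hit	000585	-	58	179	361	58
no_hit	000560	-	73	335	213	56
no_hit	001159	-	44	143	352	53
no_hit	000545	-	102	227	213	49
no_hit	000464	-	102	191	241	49
no_hit	000424	-	73	167	241	45
no_hit	000858	-	87	239	167	44
no_hit	000753	-	58	227	176	42
no_hit	000837	-	58	143	231	41
no_hit	000653	-	29	72	305	41
no_hit	000964	-	58	155	222	41
no_hit	000795	-	73	155	204	40
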