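compound	target	dg_bind_md
Lactol	MAOB	−39.08
4′,5,7-Trihydroxy-6-prenylflavanone	MAOB	−33.27
3′-Deoxythymidine	MAOB	−20.67
Lactol	BRAF	−54.13
6″-O-Acetylglycitin	BRAF	−47.38
Aloesol 7-glucoside	BRAF	−33.12
Amino(1H-indol-2-yl)acetic acid	BACE1	−41.07
2″-O-Acetylrutin	BACE1	−35.25
Fluocinolone	BACE1	−28.96
Amino(1H-indol-2-yl)acetic acid	GSK3β	−47.38
7-Methylinosine	GSK3β	−31.13
2′,3′-Dideoxyadenosine	GSK3β	−22.81
Quercetin 3-(6″-malonyl-glucoside)	PARP1	−46.03
Aloesol 7-glucoside	PARP1	−37.60
3′-Deoxythymidine	PARP1	−33.52
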