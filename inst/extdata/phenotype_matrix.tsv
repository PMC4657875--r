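species	abbrev	temp	none	Cb100	Ct200	Tp100	Gm25	Km100	PIA
Ralstonia pickettii	Rp	37	++	++	-	+	-	-	-
Ralstonia pickettii	Rp	30	++	++	-	-	+	-	NA
Cupriavidus metallidurans	Cm	37	++	-	-	-	-	++	-
Cupriavidus metallidurans	Cm	30	++	+	-	-	++	++	NA
Chryseobacterium gleum	Cg	37	++	-	-	-	-	++	-
Chryseobacterium gleum	Cg	30	++	-	-	+	++	++	NA
Ralstonia insidiosa	Ri	37	++	++	-	-	++	+	-
Ralstonia insidiosa	Ri	30	++	++	-	-	+	+	NA
Sphingomonas sanguinis	Ss	37	++	-	-	++	-	-	-
Sphingomonas sanguinis	Ss	30	++	++	-	+	-	-	NA
Burkholderia multivorans	Bm	37	++	++	++	-	+	+	++
Burkholderia multivorans	Bm	30	++	++	++	-	++	+	NA
Phyllobacterium myrsianacearum	Pm	37	-	-	-	-	-	-	-
Phyllobacterium myrsianacearum	Pm	30	++	-	-	++	-	-	NA
Sphingomonas paucimobilis	Sp	37	++	++	-	++	-	-	-
Sphingomonas paucimobilis	Sp	30	++	++	-	++	-	-	NA
Burkholderia cepacia	Bc	37	++	+	-	++	+	-	-
Burkholderia cepacia	Bc	30	++	-	-	+	++	-	NA
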