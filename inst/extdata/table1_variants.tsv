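family_id	gene	protein_change	cdna	consequence
430	DSP	p.G46D	c.G137A	missense
430	PPL	p.V1377E	c.T4130A	missense
305	DSP	p.R808C	c.C2422T	missense
964	DSP	p.Y895C	c.A2684G	missense
2285	DSP	p.1067_1068del	c.3201_3202del	frameshift_deletion
999	DSP	p.N1215S	c.A3644G	missense
471	DSP	p.R1340C	c.C4018T	missense
1594	DSP	p.E1723Q	c.G5167C	missense
179	PPL	p.R108C	c.C322T	missense
186	PPL	p.R108C	c.C322T	missense
387	PPL	p.E632K	c.G1894A	missense
1176	PPL	p.K1051V	c.3151_3152delinsGT	missense
1029	PPL	p.L1154V	c.C3460G	missense
44	PPL	p.E1163K	c.G3487A	missense
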