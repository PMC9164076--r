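receptor	structure_id	ligand	pubchem_id	binding_energy	hbond_residues	hydrophobic_residues
GRIN2B	7EU8	Loratadine	3957	-7.3	N/A	Trp391,Glu163,Tyr164,Asp165,Val390,Tyr389,Asp477,Tyr476,His405,Thr475,Trp166
GRIN2B	7EU8	Fexofenadine	3348	-6.8	Trp166,Trp391,Asp165	Ser469,Phe474,Thr475,Tyr476,Val390,Pro435,Tyr164
GRIN2B	7EU8	Triprolidine	5282443	-6.7	Arg755	Ala734,Glu531,Leu797,Met789,Phe460,Phe529,Ile530,Glu793,Leu752
GRIN2B	7EU8	Ebastine	3191	-6.6	Ile190	Ile691,Gln487,Glu522,Trp498,Asn521,Tyr526,Glu191,Gly196
GRIN2B	7EU8	Dimetindene	21855	-6.5	N/A	Leu792,Leu795,Asp463,Asn432,Trp796,Lys458,Thr701,Arg673,Leu699,Glu698
GRIN2B	7EU8	Terfenadine	5405	-6.4	N/A	Phe474,Trp166,Val390,Trp391,Pro435,Tyr164,Asp165,Thr433,Thr475,Tyr476
GRIN2B	7EU8	Tripelenamine	5587	-5.6	N/A	Leu752,Glu793,Phe529,Ile530,Leu797,Asn737,Ala734,Arg755,Ala794,Glu790
GRIN2B	7EU8	Emedastine	3219	-5.5	Trp166	Ser469,Pro435,Phe474,Tyr164,Val434,Thr433,Tyr476
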