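substrate	rank	synonym_group_id
fe	1	iron
iron	1	iron
lysine	1	lysine
glucose	1	glucose
lactose	1	lactose
phosphate	1	phosphate
mg/co/ni	2	mg_co_ni
aromatic amino acid	2	aromatic_aa
leucine	1	bcaa
leucine/valine	2	bcaa
branched-chain amino acid	2	bcaa
dipeptide	3	peptide_class
oligopeptide	3	peptide_class
sugar	3	sugar_class
amino acid	3	amino_acid_class
metal cation	3	metal_class
multidrug efflux	4	efflux_broad
protein	4	protein_broad
drug	4	efflux_broad
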