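substance,gamma_s,group,paper_ambiguous
glucose,4.0,glucose,FALSE
glycine,3.0,amino_acid,TRUE
alanine,4.0,amino_acid,TRUE
glutamate,3.6,amino_acid,FALSE
glutamine,3.6,amino_acid,FALSE
aspartate,3.0,amino_acid,TRUE
leucine,5.0,amino_acid,FALSE
isoleucine,5.0,amino_acid,FALSE
lysine,4.67,amino_acid,TRUE
oxalate,1.0,other_acid,FALSE
formate,2.0,other_acid,FALSE
citrate,3.0,other_acid,FALSE
malate,3.0,other_acid,FALSE
succinate,3.5,other_acid,FALSE
pyruvate,3.33,other_acid,FALSE
lactate,4.0,other_acid,FALSE
acetate,4.0,other_acid,FALSE
propionate,4.67,other_acid,FALSE
butyrate,5.0,other_acid,FALSE
oleate,5.67,other_acid,FALSE
malonate,2.67,other_acid,FALSE
cellulose,4.0,high_molecular,FALSE
cellobiose,4.0,high_molecular,FALSE
protein,4.2,high_molecular,TRUE
tripalmitin,5.69,high_molecular,FALSE
polyhydroxybutyrate,4.5,high_molecular,FALSE
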