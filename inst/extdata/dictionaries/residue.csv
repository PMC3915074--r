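ID,TERM,DESCRIPTION,ONE_LETTER_CODE,RESIDUE_KIND
RES001,ALA,Alanine,A,amino acid
RES002,ARG,Arginine,R,amino acid
RES003,ASN,Asparagine,N,amino acid
RES004,ASP,Aspartate,D,amino acid
RES005,CYS,Cysteine,C,amino acid
RES006,GLN,Glutamine,Q,amino acid
RES007,GLU,Glutamate,E,amino acid
RES008,GLY,Glycine,G,amino acid
RES009,HIS,Histidine,H,amino acid
RES010,ILE,Isoleucine,I,amino acid
RES011,LEU,Leucine,L,amino acid
RES012,LYS,Lysine,K,amino acid
RES013,MET,Methionine,M,amino acid
RES014,PHE,Phenylalanine,F,amino acid
RES015,PRO,Proline,P,amino acid
RES016,SER,Serine,S,amino acid
RES017,THR,Threonine,T,amino acid
RES018,TRP,Tryptophan,W,amino acid
RES019,TYR,Tyrosine,Y,amino acid
RES020,VAL,Valine,V,amino acid
RES021,DA,Deoxyadenosine (DNA adenine nucleotide),A,nucleobase
RES022,DT,Deoxythymidine (DNA thymine nucleotide),T,nucleobase
RES023,DG,Deoxyguanosine (DNA guanine nucleotide),G,nucleobase
RES024,DC,Deoxycytidine (DNA cytosine nucleotide),C,nucleobase
RES025,A,Adenosine (RNA adenine nucleotide),A,nucleobase
RES026,U,Uridine (RNA uracil nucleotide),U,nucleobase
RES027,G,Guanosine (RNA guanine nucleotide),G,nucleobase
RES028,C,Cytidine (RNA cytosine nucleotide),C,nucleobase
RES029,WAT,Water solvent residue,,solvent
RES030,Na+,Sodium counter-ion,,ion
RES031,Cl-,Chloride counter-ion,,ion
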