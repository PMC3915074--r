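ID,TERM,DESCRIPTION
FUN01,Hydroxyl,-OH group
FUN02,Carbonyl,C=O group
FUN03,Carboxyl,-COOH group
FUN04,Amine,Nitrogen-containing basic group
FUN05,Phosphate,-PO4 group
FUN06,Thiol,-SH group
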