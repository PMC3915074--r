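ID,TERM,DESCRIPTION,ATOMIC_NUMBER,FAMILY_ID
ELM001,H,Hydrogen,1,ELF01
ELM002,C,Carbon,6,ELF01
ELM003,N,Nitrogen,7,ELF01
ELM004,O,Oxygen,8,ELF01
ELM005,P,Phosphorus,15,ELF01
ELM006,S,Sulfur,16,ELF01
ELM007,Na,Sodium,11,ELF02
ELM008,K,Potassium,19,ELF02
ELM009,Mg,Magnesium,12,ELF03
ELM010,Ca,Calcium,20,ELF03
ELM011,Cl,Chlorine,17,ELF04
ELM012,Fe,Iron,26,ELF05
ELM013,Zn,Zinc,30,ELF05
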