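ID,TERM,DESCRIPTION
ELF01,Nonmetal,Nonmetallic main-group element
ELF02,Alkali metal,Group 1 metallic element
ELF03,Alkaline earth metal,Group 2 metallic element
ELF04,Halogen,Group 17 element
ELF05,Transition metal,d-block metallic element
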