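ID,TERM,DESCRIPTION
ELE01,PME,Particle-Mesh Ewald treatment of long-range electrostatics
ELE02,Ewald,Classical Ewald summation of periodic electrostatic interactions
ELE03,Cutoff,Truncation of electrostatic interactions beyond a distance cutoff
ELE04,Reaction field,Mean-field treatment of electrostatics beyond the cutoff
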