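ID,TERM,DESCRIPTION,CITATION,TYPE_ID,IS_COARSE_GRAIN
FF001,AMBER FF99SB,Modification of the AMBER ff99 protein force field with improved backbone dihedral parameters,Hornak et al. 2006,FFT01,false
FF002,AMBER FF14SB,AMBER protein force field with refined side-chain and backbone parameters,Maier et al. 2015,FFT01,false
FF003,AMBER FF99bsc0,AMBER nucleic-acid force field with the bsc0 alpha/gamma backbone correction,Perez et al. 2007,FFT01,false
FF004,CHARMM36,CHARMM all-atom additive force field for proteins and nucleic acids,Best et al. 2012,FFT01,false
FF005,OPLS-AA,Optimized potentials for liquid simulations all-atom force field,Jorgensen et al. 1996,FFT01,false
FF006,GROMOS 54A7,United-atom GROMOS biomolecular force field parameter set 54A7,Schmid et al. 2011,FFT01,false
FF007,TIP3P,Three-site rigid water model commonly used with AMBER and CHARMM force fields,Jorgensen et al. 1983,FFT01,false
FF008,TIP4P,Four-site rigid water model with a negative charge on a dummy site,Jorgensen et al. 1983,FFT01,false
FF009,SPC/E,Extended simple point charge rigid water model,Berendsen et al. 1987,FFT01,false
FF010,MARTINI,Coarse-grain force field mapping roughly four heavy atoms to one bead,Marrink et al. 2007,FFT01,true
FF011,AMOEBA,Polarizable force field based on atomic multipoles and induced dipoles,Ponder et al. 2010,FFT02,false
FF012,ReaxFF,Reactive force field allowing bond breaking and formation,van Duin et al. 2001,FFT03,false
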