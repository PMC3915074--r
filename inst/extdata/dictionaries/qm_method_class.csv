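ID,TERM,DESCRIPTION,FAMILY_ID
QMC01,Hartree-Fock,Mean-field self-consistent treatment of electron-electron interaction,QMF01
QMC02,Moller-Plesset,Perturbative correction to the Hartree-Fock wave function,QMF01
QMC03,DFT,Density functional theory based on the electron density,QMF01
QMC04,Configuration Interaction,Linear expansion of the wave function over excited determinants,QMF01
QMC05,Coupled-Cluster,Exponential ansatz over excitation operators,QMF01
QMC06,All valence electron restricted,Semi-empirical treatment restricted to valence electrons,QMF02
QMC07,Multi-reference,Wave function built from several reference configurations,QMF01
QMC08,Pi-electron restricted,Semi-empirical treatment restricted to pi electrons,QMF02
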