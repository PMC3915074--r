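ID,TERM,DESCRIPTION,CITATION,CLASS_ID
QM001,HF,Hartree-Fock self-consistent field method,,QMC01
QM002,MP2,Second-order Moller-Plesset perturbation theory,Moller and Plesset 1934,QMC02
QM003,MP4,Fourth-order Moller-Plesset perturbation theory,,QMC02
QM004,B3LYP,Becke three-parameter Lee-Yang-Parr hybrid exchange-correlation functional,Becke 1993,QMC03
QM005,PBE,Perdew-Burke-Ernzerhof generalized-gradient-approximation functional,Perdew et al. 1996,QMC03
QM006,PBE0,Hybrid functional mixing PBE exchange with exact Hartree-Fock exchange,Adamo and Barone 1999,QMC03
QM007,CISD,Configuration interaction with single and double excitations,,QMC04
QM008,CCSD,Coupled-cluster method with single and double excitations,,QMC05
QM009,CCSD(T),Coupled-cluster with singles and doubles and perturbative triples,,QMC05
QM010,CASSCF,Complete active space self-consistent field multi-reference method,,QMC07
QM011,AM1,Austin Model 1 semi-empirical method based on the NDDO approximation,Dewar et al. 1985,QMC06
QM012,PM3,Parametric Method 3 semi-empirical method,Stewart 1989,QMC06
QM013,QM/MM,Hybrid computational method mixing quantum chemistry and molecular mechanics,Warshel and Levitt 1976,
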