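ID,TERM,DESCRIPTION,CITATION
SOF01,AMBER,Assisted Model Building with Energy Refinement simulation package,Case et al. 2005
SOF02,GROMACS,GROningen MAchine for Chemical Simulations MD engine,Hess et al. 2008
SOF03,NAMD,Parallel MD engine designed for large biomolecular systems,Phillips et al. 2005
SOF04,CHARMM,Chemistry at HARvard Macromolecular Mechanics package,Brooks et al. 2009
SOF05,Gaussian,Electronic structure modelling package,Frisch et al. 2009
SOF06,NWChem,Open-source computational chemistry package,Valiev et al. 2010
SOF07,CPPTRAJ,Trajectory analysis program of the AMBER suite,Roe and Cheatham 2013
SOF08,VMD,Visual Molecular Dynamics visualization program,Humphrey et al. 1996
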