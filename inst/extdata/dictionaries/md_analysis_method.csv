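ID,TERM,DESCRIPTION
ANA01,RMSD,Root mean square deviation calculation
ANA02,RMSF,Root mean square fluctuation of atomic positions
ANA03,Radius of gyration,Mass-weighted spread of atoms around the centre of mass
ANA04,Principal component analysis,Eigen-decomposition of the coordinate covariance matrix
ANA05,Hydrogen bond analysis,Detection of hydrogen bonds by distance and angle criteria
ANA06,Clustering,Grouping of trajectory frames by structural similarity
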