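ID,TERM,DESCRIPTION
ENH01,Temperature replica exchange,Parallel replicas at different temperatures with periodic exchange attempts (T-REMD)
ENH02,Hamiltonian replica exchange,Parallel replicas with modified Hamiltonians and periodic exchange attempts
ENH03,Umbrella sampling,Biased windows along a reaction coordinate combined by reweighting
ENH04,Metadynamics,History-dependent bias deposited along collective variables
ENH05,Accelerated MD,Boost potential raising basins to accelerate barrier crossing
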