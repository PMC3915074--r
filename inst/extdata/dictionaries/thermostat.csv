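ID,TERM,DESCRIPTION
THE01,Berendsen,Weak-coupling thermostat rescaling velocities towards the reference temperature
THE02,Langevin,Stochastic thermostat adding friction and random forces
THE03,Nose-Hoover,Deterministic extended-ensemble thermostat with a thermal reservoir chain
THE04,Andersen,Stochastic thermostat reassigning velocities from a Maxwell distribution
THE05,Velocity rescaling,Stochastic velocity-rescaling thermostat with a correct canonical distribution
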