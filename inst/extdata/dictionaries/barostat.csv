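ID,TERM,DESCRIPTION
BAR01,Berendsen,Weak-coupling barostat rescaling the box towards the reference pressure
BAR02,Andersen,Barostat treating the box volume as an extended dynamical variable
BAR03,Parrinello-Rahman,Extended-ensemble barostat allowing box shape changes
BAR04,Monte Carlo,Barostat applying stochastic volume moves with Metropolis acceptance
BAR05,Nose-Hoover,Extended-ensemble barostat with a thermostat-like pressure piston chain
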