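ID,TERM,DESCRIPTION
CAL01,Geometry optimization,Search for a stationary point of the potential energy surface
CAL02,Frequency,Vibrational frequency calculation from the Hessian
CAL03,NMR,Prediction of nuclear magnetic resonance parameters
CAL04,Single point energy,Energy evaluation at a fixed geometry
CAL05,Molecular dynamics,Propagation of the equations of motion over time
CAL06,Minimization,Energy minimization of the molecular system
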