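ID,TERM,DESCRIPTION
CON01,SHAKE,Iterative algorithm constraining bond lengths to fixed values
CON02,LINCS,Linear constraint solver resetting constrained bonds after unconstrained steps
CON03,SETTLE,Analytical constraint algorithm for rigid water molecules
CON04,RATTLE,Velocity-Verlet variant of the SHAKE constraint algorithm
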