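ID,TERM,DESCRIPTION
ENS01,microcanonical,Constant number of particles volume and energy (NVE)
ENS02,canonical,Constant number of particles volume and temperature (NVT)
ENS03,isothermal-isobaric,Constant number of particles pressure and temperature (NPT)
ENS04,generalized,Generalized ensemble spanning several thermodynamic states
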