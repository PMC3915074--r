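ID,TERM,DESCRIPTION,BASIS_TYPE
BS001,STO-3G,Minimal basis of Slater-type orbitals expanded in three Gaussians,atomic
BS002,6-31G*,Split-valence double-zeta basis with polarization on heavy atoms,atomic
BS003,"6-311+G(d,p)",Triple-zeta basis with diffuse and polarization functions,atomic
BS004,cc-pVDZ,Correlation-consistent polarized valence double-zeta basis,atomic
BS005,cc-pVTZ,Correlation-consistent polarized valence triple-zeta basis,atomic
BS006,def2-SVP,Karlsruhe split-valence basis with polarization,atomic
BS007,PW,Plane-wave basis defined by a kinetic-energy cutoff,plane wave
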