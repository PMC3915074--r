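ID,TERM,DESCRIPTION
FFT01,classical,Fixed-charge additive potential energy function
FFT02,polarizable,Potential with explicit treatment of electronic polarization
FFT03,reactive,Potential allowing chemical bond breaking and formation
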