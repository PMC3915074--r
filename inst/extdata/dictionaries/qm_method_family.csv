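ID,TERM,DESCRIPTION
QMF01,ab initio,Methods derived from first principles without empirical parameters
QMF02,semi-empirical,Methods using empirical parameters to approximate integrals
QMF03,empirical,Methods fully parameterized against experimental data
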