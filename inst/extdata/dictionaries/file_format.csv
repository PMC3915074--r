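ID,TERM,DESCRIPTION,EXTENSION
FMT01,PDB,Protein Data Bank structure file,pdb
FMT02,AMBER NetCDF,Binary self-describing AMBER trajectory format,nc
FMT03,DCD,Binary trajectory format used by CHARMM and NAMD,dcd
FMT04,CSV,Comma-separated values table,csv
FMT05,SIMDEX_TOP,simdex fixture topology dialect,top
FMT06,SIMDEX_MDOUT,simdex fixture MD output dialect,out
FMT07,SIMDEX_QMOUT,simdex fixture QM output dialect,log
FMT08,XML,Extensible markup language document,xml
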