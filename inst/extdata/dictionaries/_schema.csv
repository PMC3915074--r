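DICTIONARY,COLUMN,KIND,TARGET
force_field,CITATION,extra,
force_field,TYPE_ID,link,force_field_type
force_field,IS_COARSE_GRAIN,boolean,
qm_method,CITATION,extra,
qm_method,CLASS_ID,link,qm_method_class
qm_method_class,FAMILY_ID,link,qm_method_family
basis_set,BASIS_TYPE,extra,
residue,ONE_LETTER_CODE,extra,
residue,RESIDUE_KIND,extra,
element,ATOMIC_NUMBER,extra,
element,FAMILY_ID,link,element_family
software,CITATION,extra,
file_format,EXTENSION,extra,
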