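KINASE_KIN01	synthetic kinase signature	SUB001_S101;u	SUB002_T202;u	SUB003_S303;u	SUB004_Y404;u
KINASE_KIN02	synthetic kinase signature	SUB005_S505;u	SUB006_T606;u	SUB007_S707;d
PERT_DRUGX	synthetic perturbation signature	SUB001_S101;d	SUB008_S808;d	SUB009_T909;d
PATH_CELLCYCLE	synthetic pathway signature	SUB002_T202	SUB010_S110	SUB011_S111
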