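test_id,grandparent,sex,estimate,ci_lower,ci_upper,p_printed
pgf_m,paternal grandfather,male,0.87,0.46,1.64,0.67
pgf_f,paternal grandfather,female,0.91,0.43,1.96,0.81
pgm_m,paternal grandmother,male,0.64,0.32,1.29,0.21
pgm_f,paternal grandmother,female,2.69,1.05,6.92,0.04
mgf_m,maternal grandfather,male,1.26,0.68,2.34,0.46
mgf_f,maternal grandfather,female,1.32,0.58,3.04,0.51
mgm_m,maternal grandmother,male,0.69,0.35,1.36,0.28
mgm_f,maternal grandmother,female,0.56,0.22,1.49,0.22
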