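participant_id,effect,n_t_C1,n_c_C1,n_d_C1,n_t_C2,n_c_C2,n_d_C2
p1,compromise,30,20,0,10,15,0
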