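{"a_d":4.3,"a_n":0.96,"b_d":0.26,"b_n":0.16,"b_d_bg":0.0027,"b_n_bg":0.0016,"tau_d_s":30,"tau_n_s":600}
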