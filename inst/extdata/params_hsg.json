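{"alpha0":0.15,"beta0":0.0467,"a_plus_c":2.19,"r_d":0.42,"h":0.275,"label":"HSG"}
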