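lens_model,a_constant,a0,a1,a2
GENERIC-118,118.0,1.27706,0.4,0.1
GENERIC-1190,119.0,,,
GENERIC-1174,117.4,0.90226,0.4,0.1
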