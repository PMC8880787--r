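tag_id	pattern
lsr.proj_quote	surface=to&pos=particle_quote
lsr.exp_ext_additive	surface=soshite
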