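tag_id	pattern
ergativity.middle	surface=oko
ergativity.middle	surface=koto;surface=aru
ergativity.effective	surface=age
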