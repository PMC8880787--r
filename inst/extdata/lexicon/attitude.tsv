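tag_id	pattern
attitude.affect_emotion	surface=ureshii
attitude.judgement_capacity	surface=sugoi
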