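tag_id	pattern
evidentiality.hearsay	surface=souda
evidentiality.appearance	surface=mitai
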