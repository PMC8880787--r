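tag_id	pattern
clausecomplex.te_cause_reason	surface=node
clausecomplex.noun	surface=koto&pos=noun
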