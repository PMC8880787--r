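tag_id	pattern
transitivity.voice_passive_active	surface=reru&pos=auxv
transitivity.voice_causative	surface=seru&pos=auxv
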