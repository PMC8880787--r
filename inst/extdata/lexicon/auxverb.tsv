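tag_id	pattern
auxverb_ic.stative_01	surface=teiru
auxverb_ben.benefactive_01	surface=kureru
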