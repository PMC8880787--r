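tag_id	pattern
negparticle.kana	surface=kana
negparticle.kane	surface=kane
negparticle.sa	surface=sa
negparticle.ne	surface=ne
negparticle.yo	surface=yo
negparticle.yona	surface=yona
negparticle.yone	surface=yone
negparticle.kane_nonfinal	surface=kane&pos=particle_nonfinal
negparticle.sa_nonfinal	surface=sa&pos=particle_nonfinal
negparticle.ne_nonfinal	surface=ne&pos=particle_nonfinal
negparticle.yo_nonfinal	surface=yo&pos=particle_nonfinal
negparticle.ne_other	surface=ne&pos=particle_other
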