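regulator	target	sign
RND3	ROCK1	inhibits
RHOA	ROCK1	activates
RND3	ROCK2	inhibits
ARF6	AAK1	activates
HGF	MET	activates
IGF1	IGF1R	activates
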