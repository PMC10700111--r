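state	component	parameter	value
not_missing	start	p	0.95
not_missing	trans	to_not_missing	0.98
not_missing	trans	to_missing	0.02
not_missing	ctmc	rate01	0.95
not_missing	ctmc	rate10	0.05
not_missing	jump	eps	0.02
not_missing	jump	q	0.9
not_missing	stickiness	a	1
not_missing	stickiness	b	1
missing	start	p	0.05
missing	trans	to_not_missing	0.02
missing	trans	to_missing	0.98
missing	ctmc	rate01	0.02
missing	ctmc	rate10	1.98
missing	jump	eps	0.02
missing	jump	q	0.1
missing	stickiness	a	1
missing	stickiness	b	1
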