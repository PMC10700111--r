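state	component	parameter	value
1	start	p	0.85
1	trans	to_1	0.97
1	trans	to_2	0.01
1	trans	to_3	0.01
1	trans	to_4	0.01
1	ctmc	rate01	0.95
1	ctmc	rate10	0.05
1	jump	eps	0.12
1	jump	q	0.85
1	stickiness	a	10
1	stickiness	b	1
2	start	p	0.05
2	trans	to_1	0.02
2	trans	to_2	0.96
2	trans	to_3	0.01
2	trans	to_4	0.01
2	ctmc	rate01	0.05
2	ctmc	rate10	0.05
2	jump	eps	0.9
2	jump	q	0.5
2	stickiness	a	20
2	stickiness	b	1
3	start	p	0.05
3	trans	to_1	0.02
3	trans	to_2	0.01
3	trans	to_3	0.96
3	trans	to_4	0.01
3	ctmc	rate01	0.2
3	ctmc	rate10	1.8
3	jump	eps	0.05
3	jump	q	0.5
3	stickiness	a	10
3	stickiness	b	1
4	start	p	0.05
4	trans	to_1	0.02
4	trans	to_2	0.01
4	trans	to_3	0.01
4	trans	to_4	0.96
4	ctmc	rate01	2
4	ctmc	rate10	2
4	jump	eps	0.3
4	jump	q	0.5
4	stickiness	a	1
4	stickiness	b	1
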