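id	name
1	LLP
2	LPP
3	LLPP
4	LPLP
5	LLLP
6	LPPP
7	LPPPP
8	LPPLP
9	LPLPP
10	LPLLP
11	LLPPP
12	LLPLP
13	LLLPP
14	LLLLP
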