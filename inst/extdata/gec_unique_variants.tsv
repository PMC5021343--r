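gene	variant	occurrence
GABRA1	T20I	1
GABRA4	H372P	1
GABRA5	W280R	3
GABRA5	P453L	1
GABRB2	R293W	1
GABRG3	A303T	1
GABRA4	A19T	1
GABRA5	V204I	1
GABRA5	S402A	1
GABRA6	Q237R	1
GABRB1	H421Q	1
GABRB2	R354C	2
GABRG1	S16R	1
GABRG1	S414N	1
GABRE	R472H	1
GABRE	S484L	1
GABRP	R200H	2
GABRP	S292P	1
GABRP	S293P	1
GABRP	R389N	1
GABRR2	R287H	1
GABRR2	V294I	2
GABRE	R452G	1
GABRP	V349A	5
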