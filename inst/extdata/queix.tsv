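label	population	count	variants	window_start	window_end	haplogroup
MG18	QUEIX	1	16178C;16189C;16217C	16045	16362	B
MG22	QUEIX	1	16178C;16189C;16217C;16223T	16045	16362	B
MG23	QUEIX	1	16111T;16178C;16189C;16217C	16045	16362	B
MG24	QUEIX	1	16117C;16178C;16189C;16217C	16045	16362	B
MG28	QUEIX	1	16223T;16298C;16325C;16327T;16362C	16045	16362	C
MG30	QUEIX	3	16051G;16217C;16223T;16287T;16298C;16325C;16327T	16045	16362	C
MG31	QUEIX	1	16051G;16172C;16223T;16295T;16298C;16325C;16327T;16335G	16045	16362	C
MG32	QUEIX	2	16126C;16223T;16298C;16325C;16327T	16045	16362	C
MG33	QUEIX	5	16166G;16223T;16224C;16260T;16298C;16325C;16327T;16356C	16045	16362	C
MG34	QUEIX	1	16113C;16223T;16295T;16298C;16311C;16325C	16045	16362	C
MG36	QUEIX	1	16223T;16325C;16327T	16045	16362	C
MG37	QUEIX	1	16223T;16325C;16362C	16045	16362	D
MG39	QUEIX	1	16153A;16213A;16223T;16278T;16311C;16362C	16045	16362	D
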