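label	population	count	variants	window_start	window_end	haplogroup
MG28	QUEIX	1	16223T;16298C;16325C;16327T;16362C	16045	16362	NA
MG30	QUEIX	1	16051G;16217C;16223T;16287T;16298C;16325C;16327T	16045	16362	NA
MG31	QUEIX	1	16051G;16172C;16223T;16295T;16298C;16325C;16327T;16335G	16045	16362	NA
MG32	QUEIX	1	16126C;16223T;16298C;16325C;16327T	16045	16362	NA
MG33	QUEIX	1	16166G;16223T;16224C;16260T;16298C;16325C;16327T;16356C	16045	16362	NA
MG34	QUEIX	1	16113C;16223T;16295T;16298C;16311C;16325C	16045	16362	NA
MG36	QUEIX	1	16223T;16325C;16327T	16045	16362	NA
MG27	MGNE	1	16223T;16298C;16325C;16327T	16045	16362	NA
MG29	MGNE	1	16223T;16298C;16304C;16325C;16327T	16045	16362	NA
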