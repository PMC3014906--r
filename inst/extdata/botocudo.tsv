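label	population	count	variants	window_start	window_end	haplogroup
Bot01	BOT	3	16223T;16298C;16325C;16327T	16045	16362	C
Bot02	BOT	1	16129A;16223T;16298C;16325C;16327T	16045	16362	C
Bot03	BOT	4	16051G;16223T;16298C;16325C;16327T	16045	16362	C
Bot04	BOT	4	16051G;16172C;16223T;16295T;16298C;16325C;16327T;16335G	16045	16362	C
Bot05	BOT	1	?	16045	16362	B
Bot06	BOT	1	?	16045	16362	B
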