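label	population	count	variants	window_start	window_end	haplogroup
DB_founder_A	DB	1	16111T;16223T;16290T;16319A;16362C	16045	16362	NA
DB_founder_B	DB	1	16189C;16217C	16045	16362	NA
DB_founder_C	DB	1	16223T;16298C;16325C;16327T	16045	16362	NA
DB_founder_D	DB	1	16223T;16325C;16362C	16045	16362	NA
DB_MG28_type	DB	1	16223T;16298C;16325C;16327T;16362C	16045	16362	NA
DB_MG32_type	DB	1	16126C;16223T;16298C;16325C;16327T	16045	16362	NA
DB_MG36_type	DB	1	16223T;16325C;16327T	16045	16362	NA
DB_MG37_type	DB	1	16223T;16325C;16362C	16045	16362	NA
DB_Bot02_type	DB	1	16129A;16223T;16298C;16325C;16327T	16045	16362	NA
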