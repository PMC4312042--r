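sample_id	motif	haplogroup	site
riv22	284G 294T	H6a1b1	Rivoli Corso Levi
riv25s1	126C 294T	T	Rivoli Corso Levi
riv25s2	069T 126C	J	Rivoli Corso Levi
riv68	129A 356C	U4	Rivoli Corso Levi
riv70	CRS	H	Rivoli Corso Levi
riv85	CRS	H	Rivoli Corso Levi
riv90	051G 129C 256T	U2e1	Rivoli Corso Levi
riv103	129A 256T 270T 294T	U5a1b1e	Rivoli Corso Levi
riv116	CRS	H	Rivoli Corso Levi
per4	362C	H	Rivoli La Perosa
per3F	114A 192T 256T 270T 294T	U5a2a	Rivoli La Perosa
per9F	311C	H2b	Rivoli La Perosa
per36	CRS	H	Rivoli La Perosa
mom7	CRS	H	Mombello Monferrato
mom9-1	093C 126C 153A	T2e	Mombello Monferrato
mom16	293G 311C	H24	Mombello Monferrato
mom20	069T 126C 231C 311C	J2a2c	Mombello Monferrato
mom21-1	069T 126C	J	Mombello Monferrato
lonI4	145A 223T 325C 362C	I2a	Collegno
lonI41	235G	H2a2b1	Collegno
lonI48	293G 311C	H24	Collegno
lonI63	126C 153A 183C 189C 294T	T2e	Collegno
lonII54	069T 126C 153A	J	Collegno
lonIII2	311C	H2b	Collegno
lonIII20	CRS	H	Collegno
lonIII34	256T 270T 294T	U5a1b1e	Collegno
cenII1	311C	H2b	Centallo San Gervasio
cenII39	069T 126C	J	Centallo San Gervasio
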