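position	14	24	26	36	90	91	105	114	122	125	129	142	151	156	173	175	176	181	206	208	210	213	215	221	251	256	271
MICA*001	W	T	V	C	L	Q	R	G	L	K	M	V	M	H	K	G	V	T	G	Y	W	T	S	V	Q	R	P
MICA*001	-	-	-	-	-	-	-	-	-	-	-	-	-	-	-	-	-	-	-	-	-	-	-	-	-	-	-
MICA*002	G	A	-	-	-	-	-	-	-	E	-	-	-	-	-	-	-	-	-	-	-	-	-	-	-	-	-
MICA*007	-	A	-	-	-	-	-	-	-	E	-	-	-	-	-	-	-	-	-	-	-	-	-	-	-	-	-
MICA*011	G	A	-	-	-	-	-	-	-	E	-	-	V	-	-	-	-	-	-	-	-	-	-	-	-	-	A
MICA*012	-	-	-	-	-	-	-	-	-	E	-	-	-	L	-	-	-	-	-	-	-	-	-	-	-	-	-
MICA*015	G	A	-	-	-	-	-	R	-	E	-	-	-	-	-	-	-	-	-	-	-	-	-	-	-	-	-
MICA*017	G	A	-	-	-	R	-	-	-	E	-	-	-	-	-	-	-	-	-	-	-	-	-	-	-	-	-
MICA*018	-	-	-	-	-	-	-	-	-	E	-	-	-	-	-	-	-	-	-	-	-	-	-	-	-	-	-
MICA*029	-	A	-	-	-	-	-	-	-	E	-	I	-	-	-	-	-	-	-	-	-	-	-	-	-	-	-
MICA*030	G	A	-	-	-	-	-	-	-	E	-	-	-	-	-	-	-	-	-	-	-	-	-	-	-	-	A
MICA*036	G	A	-	-	-	-	K	-	-	E	-	-	-	-	E	S	-	-	-	-	-	-	-	-	-	-	-
MICA*037	-	A	-	-	-	-	-	-	-	E	-	-	-	-	-	-	-	-	S	-	R	I	T	-	R	-	-
MICA*041	G	A	G	-	-	-	-	-	-	E	-	-	-	-	-	-	-	-	-	-	-	-	-	-	-	-	-
MICA*043	-	A	-	-	-	-	-	-	-	E	-	-	-	R	-	-	-	-	-	-	-	-	-	-	-	S	-
MICA*045	-	A	-	-	-	-	-	-	-	E	-	-	-	-	-	-	-	-	-	-	-	-	-	-	E	-	-
MICA*046	G	A	-	-	-	-	-	-	-	E	-	-	-	-	-	-	-	-	-	C	-	-	-	-	-	-	-
MICA*050	G	A	-	-	F	-	-	-	-	E	-	-	-	-	-	-	-	-	-	-	-	-	-	-	-	-	-
MICA*051	-	A	-	Y	-	-	-	-	-	E	-	-	-	-	-	-	-	-	-	-	-	-	-	-	-	-	-
MICA*004	-	A	-	Y	-	-	-	-	V	E	V	-	-	-	E	S	-	R	S	-	R	-	T	-	-	-	-
MICA*005	-	A	-	Y	-	-	-	-	-	E	V	-	-	-	-	-	-	-	S	-	R	-	T	-	R	-	-
MICA*006	-	A	-	Y	-	-	-	-	V	E	V	-	-	-	E	S	I	-	S	-	R	-	T	-	-	-	-
MICA*008	-	A	-	Y	-	-	-	-	-	E	V	-	-	-	E	-	-	-	S	-	R	I	T	-	R	-	-
MICA*009	-	A	-	Y	-	-	-	-	V	E	V	-	-	-	E	S	-	-	S	-	R	-	T	-	-	-	-
MICA*016	-	A	-	Y	-	-	-	-	-	E	V	-	-	-	E	-	-	-	S	-	R	-	T	L	-	-	-
MICA*019	-	A	-	Y	-	-	-	-	-	E	V	-	-	-	E	S	-	-	S	-	R	I	T	-	R	-	-
MICA*024	-	A	-	Y	-	-	-	-	-	E	V	-	-	-	E	-	-	-	S	-	R	-	T	-	-	-	-
MICA*028	-	A	-	Y	-	-	-	-	-	E	V	-	-	-	E	-	-	-	-	-	-	-	-	-	-	-	-
MICA*033	-	A	-	Y	-	-	-	-	-	E	V	-	-	-	E	S	-	-	S	-	R	I	T	-	R	-	-
MICA*042	-	A	-	Y	-	-	-	-	-	E	-	-	-	-	-	-	-	-	S	-	R	I	T	-	R	-	-
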