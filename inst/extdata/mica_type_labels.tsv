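allele	type
MICA*001	type_I
MICA*002	type_I
MICA*007	type_I
MICA*011	type_I
MICA*012	type_I
MICA*015	type_I
MICA*017	type_I
MICA*018	type_I
MICA*029	type_I
MICA*030	type_I
MICA*036	type_I
MICA*037	type_I
MICA*041	type_I
MICA*043	type_I
MICA*045	type_I
MICA*046	type_I
MICA*050	type_I
MICA*051	type_I
MICA*004	type_II
MICA*005	type_II
MICA*006	type_II
MICA*008	type_II
MICA*009	type_II
MICA*016	type_II
MICA*019	type_II
MICA*024	type_II
MICA*028	type_II
MICA*033	type_II
MICA*042	type_II
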