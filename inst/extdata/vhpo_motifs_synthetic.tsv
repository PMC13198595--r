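pdb_id	motif_index	ref_position	expected_residue	role
1UP8	1	330	K	catalytic
1UP8	1	334	R	vanadate_binding
1UP8	1	338	S	vanadate_binding
1UP8	2	410	H	vanadate_binding
1UP8	2	415	R	vanadate_binding
1UP8	3	480	R	vanadate_binding
1UP8	3	486	H	covalent_his
1UP8	3	490	K	catalytic
5LPC	1	330	K	catalytic
5LPC	1	334	R	vanadate_binding
5LPC	1	338	S	vanadate_binding
5LPC	2	410	H	vanadate_binding
5LPC	2	415	R	vanadate_binding
5LPC	3	480	R	vanadate_binding
5LPC	3	486	H	covalent_his
5LPC	3	490	K	catalytic
5AA6	1	330	K	catalytic
5AA6	1	334	R	vanadate_binding
5AA6	1	338	S	vanadate_binding
5AA6	2	410	H	vanadate_binding
5AA6	2	415	R	vanadate_binding
5AA6	3	480	R	vanadate_binding
5AA6	3	486	H	covalent_his
5AA6	3	490	K	catalytic
4CIT	1	250	K	catalytic
4CIT	1	254	R	vanadate_binding
4CIT	1	258	S	vanadate_binding
4CIT	2	320	H	vanadate_binding
4CIT	2	325	R	vanadate_binding
4CIT	3	390	R	vanadate_binding
4CIT	3	396	H	covalent_his
4CIT	3	400	K	catalytic
1IDQ	1	350	K	catalytic
1IDQ	1	354	R	vanadate_binding
1IDQ	1	358	S	vanadate_binding
1IDQ	2	440	H	vanadate_binding
1IDQ	2	445	R	vanadate_binding
1IDQ	3	520	R	vanadate_binding
1IDQ	3	526	H	covalent_his
1IDQ	3	530	K	catalytic
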