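source	soil	medium	n	mpn	printed_total
BS	SF	JMV	5	7.67	11.00
BS	SF	NFb	0	0	11.00
BS	SF	JNFb	3	3.33	11.00
BS	SF	LGI	0	0	11.00
BS	SF	LGI-P	0	0	11.00
BS	CH	JMV	0	0	7.67
BS	CH	NFb	0	0	7.67
BS	CH	JNFb	5	7.67	7.67
BS	CH	LGI	0	0	7.67
BS	CH	LGI-P	0	0	7.67
BS	ORG	JMV	10	16.00	18.67
BS	ORG	NFb	0	0	18.67
BS	ORG	JNFb	2	1.33	18.67
BS	ORG	LGI	1	1.33	18.67
BS	ORG	LGI-P	0	0	18.67
TR	SF	JMV	7	18.00	27.33
TR	SF	NFb	2	3.00	27.33
TR	SF	JNFb	2	3.33	27.33
TR	SF	LGI	2	2.00	27.33
TR	SF	LGI-P	1	1.00	27.33
TR	CH	JMV	9	9.00	19.67
TR	CH	NFb	2	2.67	19.67
TR	CH	JNFb	4	4.00	19.67
TR	CH	LGI	3	4.00	19.67
TR	CH	LGI-P	0	0	19.67
TR	ORG	JMV	5	8.00	15.33
TR	ORG	NFb	0	0	15.33
TR	ORG	JNFb	5	6.33	15.33
TR	ORG	LGI	0	1.00	15.33
TR	ORG	LGI-P	0	0	15.33
LR	SF	JMV	5	10.00	25.33
LR	SF	NFb	1	1.00	25.33
LR	SF	JNFb	4	8.33	25.33
LR	SF	LGI	1	3.33	25.33
LR	SF	LGI-P	1	2.67	25.33
LR	CH	JMV	2	3.67	9.33
LR	CH	NFb	0	1.00	9.33
LR	CH	JNFb	1	2.33	9.33
LR	CH	LGI	1	2.33	9.33
LR	CH	LGI-P	0	0	9.33
LR	ORG	JMV	6	5.67	24.67
LR	ORG	NFb	1	1.00	24.67
LR	ORG	JNFb	5	7.67	24.67
LR	ORG	LGI	5	9.00	24.67
LR	ORG	LGI-P	0	1.33	24.67
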