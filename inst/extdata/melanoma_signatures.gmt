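pigmentation	melanoma pigmentation state markers	MITF	MLANA	TRPM1	DCT	TYR
SMC	starved-like melanoma cell state markers	CD36	DLX5	IP6K3	PAX3	TRIM67
invasive	melanoma invasive state markers	AXL	CYR61	TCF4	LOXL2	TNC	WNT5A
NCSC	neural crest cell-like state markers	AQP1	GFRA2	L1CAM	NGFR	SLC22A17	TMEM176B
yap1_activation	YAP1 activation targets	CYR61	CTGF	TEAD4	LATS2	CRIM1
anoikis_resistance	anoikis resistance markers	S100A7A	MTPN	ATP10B	S100A8	RSAD2	RENBP	CDHR1	CD36
er_activation	oestrogen receptor activation markers	GATA4	SDK2	EGR3	IL19	GSG1L	RSPO1	PGR	IL24	PDZK1
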