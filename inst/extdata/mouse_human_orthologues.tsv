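human	mouse
MITF	Mitf
MLANA	Mlana
TRPM1	Trpm1
DCT	Dct
TYR	Tyr
CD36	Cd36
DLX5	Dlx5
IP6K3	Ip6k3
PAX3	Pax3
TRIM67	Trim67
AXL	Axl
CYR61	Cyr61
TCF4	Tcf4
LOXL2	Loxl2
TNC	Tnc
WNT5A	Wnt5a
AQP1	Aqp1
GFRA2	Gfra2
L1CAM	L1cam
NGFR	Ngfr
SLC22A17	Slc22a17
TMEM176B	Tmem176b
CTGF	Ctgf
TEAD4	Tead4
LATS2	Lats2
CRIM1	Crim1
S100A7A	S100a7a
MTPN	Mtpn
ATP10B	Atp10b
S100A8	S100a8
RSAD2	Rsad2
RENBP	Renbp
CDHR1	Cdhr1
GATA4	Gata4
SDK2	Sdk2
EGR3	Egr3
IL19	Il19
GSG1L	Gsg1l
RSPO1	Rspo1
PGR	Pgr
IL24	Il24
PDZK1	Pdzk1
GRPR	Grpr
CDH1	Cdh1
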