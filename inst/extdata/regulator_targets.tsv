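regulator	target	sign
NRF2	Vcp	+1
NRF2	Prdx1	+1
NRF2	Gstp1	+1
NRF2	Gstm1	+1
NRF2	Cbr1	+1
NRF2	Bhmt	+1
NRF2	Fabp1	-1
NRF2	Hsp90b1	0
NRF2	Rplp0	0
NRF2	Serpina3k	0
NRF2	Uox	0
PPARA	Scp2	+1
PPARA	Gstp1	-1
PPARA	Ftcd	-1
PPARA	Fabp1	+1
PPARA	Dbi	+1
PPARA	Cps1	-1
PPARA	Cat	+1
PPARA	Ass1	-1
PPARA	Aldob	-1
PPARA	Aldh2	-1
PPARA	Acox1	+1
PPARA	Acat1	0
PPARA	Hacl1	0
PPARA	Hadha	0
PPARA	Hsd17b10	0
PPARA	Krt8	0
PPARA	Pc	0
PPARA	Por	0
PPARA	Acadvl	0
PPARA	Arg1	0
PPARA	Ech1	0
PPARA	Ehhadh	0
PPARA	Gstz1	0
PPARA	Hsd17b4	0
PPARA	Selenbp1	0
CTNNB1	Ca3	0
CTNNB1	Cyp2a6	0
CTNNB1	Cyp2e1	0
CTNNB1	Glul	0
CTNNB1	Oat	0
CTNNB1	Rgn	0
ACOX1	Acox1	0
ACOX1	Acsl1	0
ACOX1	Cat	0
ACOX1	Hspa5	0
ACOX1	Acadvl	0
ACOX1	Ehhadh	0
ACOX1	Uox	0
RXRA	Acox1	0
RXRA	Fabp1	0
RXRA	Gpt	0
RXRA	Gpx1	0
NR1I2	Acox1	0
NR1I2	Bhmt	0
NR1I2	Glul	0
NR1I2	Gstm1	0
NR1I2	Gstp1	0
NR1I2	Hmgcs2	0
NR1I2	Por	0
NR1I2	Tf	0
NR1I2	Uox	0
MED1	Acox1	0
MED1	Gstp1	0
MED1	Scp2	0
MED1	Ehhadh	0
MED1	Hsd17b4	0
LEP	Acox1	0
LEP	Aldob	0
LEP	Ass1	0
LEP	Cps1	0
LEP	Cyp2e1	0
LEP	Gpx1	0
LEP	Prdx1	0
LEP	Scp2	0
LEP	Acadvl	0
LEP	Ech1	0
LEP	Ehhadh	0
LEP	Ephx2	0
LEP	Sod1	0
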