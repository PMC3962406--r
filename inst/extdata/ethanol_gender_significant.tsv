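accession	gene_symbol	function	protein_name	116:114 log2R	115:113 log2R
B2KGV2	Cps1	fatty acid metabolism	Carbamoyl-phosphate synthase	3.11	-
A2ATU0	Dhtkd1	alcohol metabolism	Probable 2-oxoglutarate dehydrogenase E1	3.1	-
P10649	Gstm1	oxidation reduction	Glutathione S-transferase Mu 1	2.92	1.37
A0ZNJ2	Hibadh	oxidation reduction	3-hydroxyisobutyrate dehydrogenase	2.76	-
Q8R0Y6	Aldh1l1	oxidation reduction	10-formyltetrahydrofolate dehydrogenase	2.55	-
Q3UER1	Aldob	alcohol metabolism	Fructose-bisphosphate aldolase	2.09	-
Q91XG2	Cyp2a4	oxidation reduction	Cytochrome P450, family 2A4	2.07	-
Q3UWN2	Aass	oxidation reduction	Putative uncharacterized protein	2.01	-
Q7TSZ0	Hspa9	chaperone	Heat shock protein 9	2.01	-
Q3UJ34	Ass1	oxidation reduction	Argininosuccinate synthase	1.95	-
Q3UKT3	Oat	amino acid metabolism	Putative uncharacterized protein	1.87	-
Q544B1	Aldh2	alcohol metabolism	Aldehyde dehydrogenase 2	1.79	-
Q546G4	Krt8	developmental process	Albumin 1	1.63	2.07
Q3TCQ3	Pcx	energy production	Putative uncharacterized protein	1.57	-
A2A6J8	Tnni2	developmental process	Troponin I, skeletal, fast 2	1.57	2.21
Q91XD4	Ftcd	fatty acid metabolism	Formimidoyltransferase-cyclodeaminase	1.45	-1.69
P37040	Por	oxidation reduction	NADPH--cytochrome P450 reductase	1.44	-
B1AWX7	Aldh1b1	alcohol metabolism	Aldehyde dehydrogenase 1B1	1.42	-
Q566C3	Gpt	amino acid metabolism	Alanine aminotransferase 1	1.4	-
Q3TIT9	Acaa2	fatty acid metabolism	Acetyl-Coenzyme A acyltransferase 2	1.37	-
Q921I1	Tf	serum carrier protein	Serotransferrin	1.37	1.9
D3Z106	Acsm1	fatty acid metabolism	Uncharacterized protein	1.36	-
Q6GTG6	Acsl1	fatty acid metabolism	Long-chain-fatty-acid--CoA ligase 1	1.29	-
Q05421	Cyp2e1	oxidation reduction	Cytochrome P450 2E1	1.26	1.59
Q8R086	Suox	oxidation reduction	Sulfite oxidase, mitochondrial	1.24	-
P63038	Hspd1	chaperone	60 kDa heat shock protein	1.14	-
P08249	Mdh2	oxidation reduction	Malate dehydrogenase	1.06	1.49
Q9CZN7	Shmt2	fatty acid metabolism	Serine hydroxymethyltransferase	1.02	-
P15105	Glul	fatty acid metabolism	Glutamine synthetase	1.01	-
Q3TXS9	Rps2	DNA binding	Putative uncharacterized protein	-1.29	-2.51
Q3U6S1	Vim	developmental process	Putative uncharacterized protein	-1.55	-1.38
Q5FW97	Eno1	alcohol metabolism	Enolase	-1.83	-1.17
P32020	Scp2	fatty acid metabolism	Non-specific lipid-transfer protein	-1.97	-
P10853	Hist1h2bf	DNA binding	Histone H2B type 1-F	-1.98	-3.89
P16015	Ca3	fatty acid metabolism	Carbonic anhydrase 3	-2.14	-4.98
Q91W60	Itih4	metabolism	Inter alpha-trypsin inhibitor, heavy chain 4	-	4.33
Q545Y3	Tpm1	developmental process	Putative uncharacterized protein	-	2.99
A2A4Z2	Tnnc2	developmental process	Troponin C2, fast	-	2.92
Q8CF02	Fam25	N/A	Protein FAM25	-	2.29
Q02819	Nucb1	DNA binding	Nucleobindin-1	-	2.01
P56135	Atp5j	energy production	ATP synthase-coupling factor 6	-	1.93
P63242	Eif5a	apoptosis process	Eukaryotic translation initiation factor 5A-1	-	1.85
Q5FWJ5	actg1-b	DNA binding	Hnrpk protein	-	1.83
Q8C7E7	Stbd1	amino acid metabolism	Starch-binding domain-containing protein 1	-	1.71
Q8VDD5	Myh9	developmental process	Myosin-9	-	1.65
Q58E70	Krt8	developmental process	Putative uncharacterized protein	-	1.54
P27773	Pdia3	oxidation reduction	Protein disulfide-isomerase A3	-	1.51
Q3UKP2	Hpx	signaling/transcription	Hemopexin, isoform CRA_f	-	1.47
Q91XF8	Apoa4	fatty acid metabolism	Apolipoprotein A-IV	-	1.46
Q544Y7	Cfl1	developmental process	Cofilin 1, non-muscle	-	1.41
Q4KL76	Hspe1	chaperone	Heat shock protein 1 (Chaperonin 10)	-	1.4
Q922C8	P4hb	oxidation reduction	Prolyl 4-hydroxylase, beta polypeptide	-	1.36
Q3UEK9	Ahsg	developmental process	Alpha-2-HS-glycoprotein, isoform CRA_a	-	1.32
Q99K47	Fga	signaling/transcription	Fibrinogen, alpha polypeptide	-	1.28
P19157	Gstp1	oxidation reduction	Glutathione S-transferase P 1	-	1.28
E0CXN5	Gpd1	oxidation reduction	Uncharacterized protein	-	1.25
Q9CQB4	Uqcrb	oxidation reduction	MCG67985	-	1.22
A8DUK0	Hbb-b1	transport	Beta-globin	-	1.2
Q4FJX9	Sod2	oxidation reduction	Superoxide dismutase	-	1.1
Q54AH9	Hbb	transport	Beta-2-globin (Fragment)	-	1.08
B2RXY7	Cbr1	oxidation reduction	Carbonyl reductase 1	-	1.02
Q9DCY1	Ppib	protein folding	Peptidyl-prolyl cis-trans isomerase	-	-1.02
Q91V38	Hsp90b1	chaperone	Heat shock protein 90, beta (Grp94)	-	-1.06
Q3TZJ3	Hspa8	chaperone	Putative uncharacterized protein	-	-1.16
D2KHZ9	Gapdh	oxidation reduction	Glyceraldehyde-3-phosphate dehydrogenase	-	-1.28
P62264	Rps14	signaling/transcription	40S ribosomal protein S14	-	-1.3
Q3TDN8	Bphl	signaling/transcription	Putative uncharacterized protein	-	-1.34
P14152	Mdh1	oxidation reduction	Malate dehydrogenase	-	-1.37
Q9JMH6	Txnrd1	oxidation reduction	Thioredoxin reductase 1	-	-1.37
P49429	Hpd	oxidation reduction	4-hydroxyphenylpyruvate dioxygenase	-	-1.58
O88844	Idh1	oxidation reduction	Isocitrate dehydrogenase [NADP]	-	-1.63
Q3V2F7	Fabp1	fatty acid metabolism	Fatty acid binding protein 1, liver	-	-1.74
Q3U9G2	Hspa5	chaperone	Putative uncharacterized protein	-	-1.75
Q3TY87	Fah	amino acid metabolism	Putative uncharacterized protein	-	-1.77
Q99JY0	Hadhb	oxidation reduction	Trifunctional enzyme subunit beta	-	-1.78
Q4FZE6	Rps7	signaling/transcription	Putative uncharacterized protein	-	-1.9
P05784	Krt18	developmental process	Keratin, type I cytoskeletal 18	-	-1.97
P17563	Selenbp1	signaling/transcription	Selenium-binding protein 1	-	-1.98
Q5EBH4	Dmgdh	oxidation reduction	Dimethylglycine dehydrogenase	-	-2.06
Q99KR3	Lactb2	fatty acid metabolism	Beta-lactamase-like protein 2	-	-2.21
Q53ZU7	Prdx6	oxidation reduction	Peroxiredoxin 6	-	-2.3
Q5M9M5	Rpl23a	DNA binding	MCG10806	-	-2.62
O35459	Bhmt	amino acid metabolism	Betaine--homocysteine S-methyltransferase 1	-	-2.74
Q3UIA9	Fh1	fatty acid metabolism	Fumarate hydratase 1	-	-2.87
Q63880	Es31	alcohol metabolism	Liver carboxylesterase 31	-	-3.19
Q56A15	Cycs	energy production	Cytochrome c, somatic	-	-3.22
Q3V235	Phb2	DNA binding	Prohibitin 2	-	-3.22
P67778	Phb	DNA binding	Prohibitin	-	-3.43
P56480	Atp5b	energy production	ATP synthase subunit beta	-	-3.6
Q03265	Atp5a1	energy production	ATP synthase subunit alpha	-	-3.79
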