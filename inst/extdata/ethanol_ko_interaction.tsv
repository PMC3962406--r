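accession	gene_symbol	function	116:114 log2R	116:114 p	121:114 log2R	121:114 p	cluster	section
B2KGV2	Cps1	fatty acid metabolism	3.11	0.008	1.67	0.092	2	lower_right
A2ATU0	Dhtkd1	alcohol metabolism	3.10	0.003	1.62	0.004	2	lower_right
P10649	Gstm1	oxidation reduction	2.92	0.000	-0.31	0.967	3	lower_right
Q8R0Y6	Aldh1l1	oxidation reduction	2.55	0.001	0.07	0.529	2	lower_right
Q3UER1	Aldob	alcohol metabolism	2.09	0.000	0.76	0.303	2	lower_right
Q91XG2	Cyp2a4	oxidation reduction	2.07	0.038	0.76	0.211	2	lower_right
Q3UKT3	Oat	amino acid metabolism	1.87	0.001	0.61	0.737	2	lower_right
Q544B1	Aldh2	alcohol metabolism	1.79	0.000	0.69	0.064	2	lower_right
A2A6J8	Tnni2	developmental process	1.57	0.003	-0.01	0.007	2	lower_right
Q91XD4	Ftcd	fatty acid metabolism	1.45	0.005	0.00	0.732	2	lower_right
P37040	Por	oxidation reduction	1.44	0.037	0.32	0.615	2	lower_right
Q566C3	Gpt	amino acid metabolism	1.40	0.012	-0.32	0.766	2	lower_right
Q6GTG6	Acsl1	fatty acid metabolism	1.29	0.009	-1.79	0.043	3	lower_right
Q05421	Cyp2e1	oxidation reduction	1.26	0.001	-4.29	0.034	3	lower_right
P08249	Mdh2	oxidation reduction	1.06	0.024	-0.15	0.571	2	lower_right
Q9CZN7	Shmt2	fatty acid metabolism	1.02	0.040	-0.29	0.818	2	lower_right
P15105	Glul	fatty acid metabolism	1.01	0.001	-0.45	0.045	2	lower_right
P19157	Gstp1	oxidation reduction	0.90	0.011	-1.40	0.000	2	lower_right
Q8QZS6	Hmgcl	fatty acid metabolism	0.76	0.008	-1.32	0.257	2	lower_right
Q9QXE0	Hacl1	fatty acid metabolism	0.72	0.039	-0.96	0.135	2	lower_right
P54869	Hmgcs2	alcohol metabolism	0.72	0.000	-0.73	0.001	2	lower_right
P08228	Sod1	oxidation reduction	0.45	0.938	-1.71	0.001	2	lower_right
P40142	Tkt	fatty acid metabolism	0.37	0.188	-1.40	0.040	2	lower_right
Q3TV75	Uqcrc1	oxidation reduction	0.35	0.323	-1.44	0.031	2	lower_right
Q540D7	Akr1a4	alcohol metabolism	0.24	0.434	-0.89	0.032	2	lower_right
Q80XN0	Bdh1	oxidation reduction	0.19	0.517	-1.01	0.005	2	lower_right
Q8VC30	Dak	alcohol metabolism	0.16	0.230	-2.43	0.005	2	lower_right
Q63880	Es31	alcohol metabolism	0.09	0.959	-2.19	0.001	2	lower_right
Q3THH1	Pdia6	oxidation reduction	0.01	0.804	-1.37	0.029	2	lower_right
Q3UEM0	Akr1c6	fatty acid metabolism	-0.04	0.223	-1.59	0.001	2	lower_right
Q9QXD6	Fbp1	fatty acid metabolism	-0.09	0.344	-2.35	0.002	2	lower_right
Q9WVL0	Gstz1	oxidation reduction	-0.17	0.653	-2.42	0.012	2	lower_right
Q5FW57	Gm4952	fatty acid metabolism	-0.24	0.299	-1.93	0.050	2	lower_right
Q9CPY7	Lap3	metabolism	-0.25	0.255	-2.33	0.000	2	lower_right
Q3T9Z2	Grhpr	oxidation reduction	-0.27	0.276	-2.05	0.012	2	lower_right
Q91W49	Ehhadh	oxidation reduction	-0.31	0.091	-2.29	0.000	2	lower_right
Q91XE0	Glyat	fatty acid metabolism	-0.52	0.426	-1.65	0.011	2	lower_right
P48036	Anxa5	fatty acid metabolism	-0.60	0.220	-2.09	0.011	2	lower_right
Q542K4	Cat	oxidation reduction	-0.78	0.001	-2.62	0.000	2	lower_right
B2RTM0	hist2h4	DNA binding	-1.10	0.098	-2.58	0.046	2	lower_right
P16015	Ca3	fatty acid metabolism	-2.14	0.000	-3.43	0.000	2	lower_right
P52503	Ndufs6	oxidation reduction	-0.01	1.000	1.17	0.048	2	upper_left
Q58E70	Krt8	developmental process	-0.86	0.046	0.40	0.095	2	upper_left
Q5FW97	Eno1	alcohol metabolism	-1.83	0.000	-0.17	0.056	2	upper_left
B1ASG5	Uqcrh	oxidation reduction	-2.91	0.183	1.61	0.039	3	upper_left
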