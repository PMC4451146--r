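id	sex	father_id	mother_id	birth_year	death_year	emigration_year	parish	social_class	twin	first_born	married	marriage_year	n_children
g4_18	male	g3_51	g3_24	1798.04	1811.6	NA	parish2	rich	FALSE	TRUE	FALSE	NA	0
g3_51	male	g2_119	g2_99	1771.35	1805.95	NA	parish2	rich	FALSE	FALSE	TRUE	1792.78	5
g3_24	female	g2_57	g2_34	1760.3	1822.22	NA	parish2	rich	FALSE	FALSE	TRUE	1792.78	5
g2_119	male	g1_m29	g1_f29	1736.15	1821.54	NA	parish2	rich	FALSE	FALSE	TRUE	1755.91	11
g2_57	male	g1_m15	g1_f15	1734.35	1803.03	NA	parish2	poor	FALSE	TRUE	TRUE	1759.1	10
g2_99	female	g1_m25	g1_f25	1731.32	1801.13	NA	parish2	rich	FALSE	FALSE	TRUE	1755.91	11
g2_34	female	g1_m10	g1_f10	1737.01	1790.36	NA	parish2	poor	FALSE	FALSE	TRUE	1759.1	10
g1_m29	male	NA	NA	1701.45	1760.89	NA	parish2	rich	FALSE	NA	TRUE	1726.84	5
g1_m15	male	NA	NA	1699.95	1760.38	NA	parish2	poor	FALSE	NA	TRUE	1734.2	2
g1_m25	male	NA	NA	1697.19	1754.49	NA	parish2	rich	FALSE	NA	TRUE	1723.19	5
g1_m10	male	NA	NA	1699.33	1741.87	NA	parish2	poor	FALSE	NA	TRUE	1723.22	6
g1_f29	female	NA	NA	1704.47	1755.24	NA	parish2	rich	FALSE	NA	TRUE	1726.84	5
g1_f15	female	NA	NA	1711.02	1759.26	NA	parish2	poor	FALSE	NA	TRUE	1734.2	2
g1_f25	female	NA	NA	1703.63	1791.33	NA	parish2	rich	FALSE	NA	TRUE	1723.19	5
g1_f10	female	NA	NA	1703.53	1739.22	NA	parish2	poor	FALSE	NA	TRUE	1723.22	6
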