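read_id	identity	start	width
r0001	99.78	943	100
r0002	99.97	471	100
r0003	72.23	1088	100
r0004	71.84	703	100
r0005	73.75	917	100
r0006	99.48	1413	100
r0007	85.82	216	100
r0008	97.7	1882	100
r0009	98.73	281	100
r0010	98.37	1517	100
r0011	97.73	1429	100
r0012	79.85	152	100
r0013	99.08	881	100
r0014	98.3	21	100
r0015	73.52	657	100
r0016	90.36	274	100
r0017	97.77	50	100
r0018	99.99	374	100
r0019	97.49	1415	100
r0020	98.1	769	100
r0021	90.14	892	100
r0022	98.7	1078	100
r0023	97.85	974	100
r0024	98.36	451	100
r0025	98.37	1573	100
r0026	97.44	429	100
r0027	78.42	1017	100
r0028	99.2	1545	100
r0029	97.94	925	100
r0030	98.8	713	100
r0031	97.07	1676	100
r0032	97.23	28	100
r0033	99.03	939	100
r0034	93.65	866	100
r0035	99.04	1205	100
r0036	99.62	555	100
r0037	90.32	1157	100
r0038	85.59	1024	100
r0039	97.46	928	100
r0040	98.27	732	100
r0041	99.94	1834	100
r0042	98.47	346	100
r0043	99.2	517	100
r0044	98.71	1085	100
r0045	97.6	625	100
r0046	98.41	25	100
r0047	72.08	950	100
r0048	99.08	628	100
r0049	97.64	211	100
r0050	88.84	1548	100
r0051	97.27	1770	100
r0052	99.3	597	100
r0053	99.78	239	100
r0054	98.8	1692	100
r0055	97.73	1714	100
r0056	73.66	1727	100
r0057	97.34	1384	100
r0058	73.12	578	100
r0059	97.84	426	100
r0060	99.53	508	100
r0061	98.14	612	100
r0062	91.89	363	100
r0063	99.02	558	100
r0064	96.29	1876	100
r0065	95.76	1772	100
r0066	98.91	182	100
r0067	97.49	99	100
r0068	75.35	1577	100
r0069	99.72	238	100
r0070	99.03	943	100
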