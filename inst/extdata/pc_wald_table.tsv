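predictor	se	t	p
PC1	1.1638	7.8235	5.14e-15
PC2	0.0008	14.7641	0
PC3	0.0013	-11.1861	4.77e-29
PC4	0.0014	-13.4629	2.59e-41
PC5	0.0019	-12.9322	2.96e-38
PC6	0.0015	-2.1592	0.030837
PC7	0.0022	13.8375	1.51e-43
PC8	0.0019	-0.0055	0.995623
PC9	0.0023	-9.0287	1.74e-19
PC10	0.0026	1.2018	0.22944
PC11	0.0026	-2.1862	0.028801
PC12	0.0027	1.6188	0.1055
PC13	0.0032	-7.2077	5.69e-13
PC14	0.0033	-8.3964	4.61e-17
PC15	0.0034	-0.7858	0.431973
PC16	0.0035	1.8389	0.065923
PC17	0.0037	0.0854	0.931964
PC18	0.0036	5.9441	2.78e-9
PC19	0.0035	1.8050	0.07108
PC20	0.0036	-6.9300	4.21e-12
PC21	0.0040	4.9057	9.31e-7
PC22	0.0040	-4.4528	8.47e-6
PC23	0.0043	11.6463	2.40e-31
PC24	0.0045	-4.8968	9.74e-7
PC25	0.0048	-9.4881	2.35e-21
PC26	0.0047	0.7119	0.476501
PC27	0.0047	-0.6445	0.519277
PC28	0.0050	-2.6172	0.008865
PC29	0.0053	0.9396	0.347413
PC30	0.0054	-6.5354	6.34e-11
PC31	0.0050	-1.4328	0.151915
PC32	0.0054	-0.5211	0.602287
PC33	0.0052	2.2693	0.023249
PC34	0.0057	-0.6697	0.503072
PC35	0.0058	-0.1642	0.869595
PC36	0.0056	6.0392	1.55e-9
PC37	0.0059	-1.5046	0.132437
PC38	0.0061	-2.5012	0.012377
PC39	0.0060	0.5841	0.559178
PC40	0.0062	2.9399	0.003284
PC41	0.0065	3.0751	0.002104
PC42	0.0065	-6.5521	5.67e-11
PC43	0.0065	-3.3909	0.000697
PC44	0.0068	-0.2496	0.802873
PC45	0.0063	3.0721	0.002125
PC46	0.0065	-1.5325	0.125403
PC47	0.0064	-1.5169	0.1293
PC48	0.0067	-2.3565	0.01845
PC49	0.0069	1.7933	0.072918
PC50	0.0071	-3.3454	0.000822
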