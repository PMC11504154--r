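CIN70_SYNTHETIC	synthetic 70-gene placeholder for a chromosomal-instability proliferation signature; replace with the published membership for real data	PROLIF01	PROLIF02	PROLIF03	PROLIF04	PROLIF05	PROLIF06	PROLIF07	PROLIF08	PROLIF09	PROLIF10	PROLIF11	PROLIF12	PROLIF13	PROLIF14	PROLIF15	PROLIF16	PROLIF17	PROLIF18	PROLIF19	PROLIF20	PROLIF21	PROLIF22	PROLIF23	PROLIF24	PROLIF25	PROLIF26	PROLIF27	PROLIF28	PROLIF29	PROLIF30	PROLIF31	PROLIF32	PROLIF33	PROLIF34	PROLIF35	PROLIF36	PROLIF37	PROLIF38	PROLIF39	PROLIF40	PROLIF41	PROLIF42	PROLIF43	PROLIF44	PROLIF45	PROLIF46	PROLIF47	PROLIF48	PROLIF49	PROLIF50	PROLIF51	PROLIF52	PROLIF53	PROLIF54	PROLIF55	PROLIF56	PROLIF57	PROLIF58	PROLIF59	PROLIF60	PROLIF61	PROLIF62	PROLIF63	PROLIF64	PROLIF65	PROLIF66	PROLIF67	PROLIF68	PROLIF69	PROLIF70
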