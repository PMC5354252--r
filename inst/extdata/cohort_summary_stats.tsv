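# Published per-population-by-sex summary statistics of the four-population study cohort.
# n_height / n_melanin / n_nose: sample sizes for height, melanin index, and 3D nose traits.
# Units: height cm; melanin index dimensionless (100*log10(1/reflectance at 650 nm));
# linear distances mm; areas mm^2. Values are mean and standard deviation (sd_*).
population	sex	n_height	n_melanin	n_nose	mean_height	sd_height	mean_melanin_index	sd_melanin_index	mean_nares_width	sd_nares_width	mean_alar_base_width	sd_alar_base_width	mean_nasal_height	sd_nasal_height	mean_nasal_ridge_length	sd_nasal_ridge_length	mean_nasal_tip_protrusion	sd_nasal_tip_protrusion	mean_external_surface_area	sd_external_surface_area	mean_nostril_area	sd_nostril_area
W.African	male	10	6	10	179.89	6.48	59.23	9.68	45.36	2.74	45.31	2.61	51.31	2.36	46.31	2.63	15.94	1.44	1782.13	122.92	70.17	10.41
W.African	female	30	28	30	164.68	8.61	60.27	11.34	39.50	2.95	40.57	2.56	49.15	3.04	43.82	2.76	14.43	0.98	1477.42	167.39	57.18	9.75
E.Asian	male	43	33	43	173.02	6.79	31.42	2.94	38.55	2.28	39.98	2.31	52.35	2.52	47.14	2.59	15.81	1.35	1604.73	154.02	57.59	7.61
E.Asian	female	84	74	84	159.94	6.23	32.63	2.94	34.35	2.02	36.60	1.93	48.76	2.03	43.41	2.24	14.47	1.11	1315.35	100.95	45.40	4.77
N.European	male	91	91	91	181.00	7.72	26.71	2.68	34.29	2.42	35.66	2.53	51.59	2.64	47.82	2.78	17.62	1.25	1758.72	153.36	54.46	5.97
N.European	female	145	144	145	167.15	6.70	28.19	2.60	30.91	2.07	33.00	1.98	48.62	2.11	44.78	2.37	16.43	1.02	1470.61	118.68	45.80	5.13
S.Asian	male	42	35	42	173.91	6.13	38.50	5.82	37.47	2.59	37.77	2.57	50.81	2.34	46.59	2.35	16.60	1.23	1719.14	134.48	60.83	8.87
S.Asian	female	31	26	31	157.74	6.72	39.89	4.72	33.20	1.89	34.33	1.92	47.31	2.13	43.57	2.47	15.68	1.26	1422.48	122.86	48.52	6.48
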