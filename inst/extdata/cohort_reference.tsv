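variable	test	g1_n	g1_mean	g1_sd	g2_n	g2_mean	g2_sd	a	b	c	d	published_stat	published_effect	published_p	consistent
age_years	t	62	48.18	9.40	116	53.85	8.89	NA	NA	NA	NA	-3.976	0.620	<0.001	TRUE
education_years	t	62	12.05	4.19	116	10.91	3.79	NA	NA	NA	NA	1.846	0.285	0.067	TRUE
bmi	t	62	26.38	5.51	116	25.80	4.80	NA	NA	NA	NA	0.683	0.112	0.496	FALSE
smoking_status	chi2	NA	NA	NA	NA	NA	NA	37	79	20	42	1.938	0.104	0.585	FALSE
alcohol_status	chi2	NA	NA	NA	NA	NA	NA	4	58	3	113	4.410	0.157	0.353	FALSE
n_pregnancies	t	62	2.07	1.05	116	1.95	0.99	NA	NA	NA	NA	0.732	0.118	0.465	FALSE
sex_of_children	chi2	NA	NA	NA	NA	NA	NA	50	52	100	70	2.477	0.118	0.116	TRUE
menopause	chi2	NA	NA	NA	NA	NA	NA	21	41	67	49	9.223	-0.228	0.002	TRUE
hormone_replacement_therapy	chi2	NA	NA	NA	NA	NA	NA	3	59	9	107	0.548	-0.055	0.459	TRUE
duration_illness_years	t	62	19.31	11.65	116	18.45	11.65	NA	NA	NA	NA	0.468	0.074	0.640	TRUE
n_mood_episodes	t	62	9.86	12.02	116	9.12	12.14	NA	NA	NA	NA	0.377	0.061	0.707	TRUE
n_depressive_episodes	t	62	7.97	9.81	116	6.50	7.21	NA	NA	NA	NA	1.137	0.171	0.257	TRUE
n_manic_episodes	t	62	3.14	4.45	116	4.50	7.18	NA	NA	NA	NA	-1.051	0.228	0.296	FALSE
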