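# Bundled free-neutral-atom reference table (atomic units).
# SYNTHETIC DATASET: alpha_ref and c6_ref are anchored to widely used
# free-atom literature values (CCSD-level alpha for Sr, Y, Zr; standard
# dipole-oscillator-strength C6 sets for the rest); wp_ref is derived from
# the one-oscillator relation C6 = (3/4) alpha^2 wp. The radial moments
# r3_ref/r4_ref (exact only for H) and the damping radii rdamp_ref are
# synthetic, constructed to be physically plausible so that every pipeline
# stage is runnable and testable without external data. Replace with a
# user-supplied table of the same schema for production use.
# columns: symbol charge alpha_ref c6_ref wp_ref r3_ref r4_ref rdamp_ref source_tag
symbol	charge	alpha_ref	c6_ref	wp_ref	r3_ref	r4_ref	rdamp_ref	source_tag
H	0	4.50	6.50	0.42798353909	7.500000000	22.500000000	3.1532	tabulated
He	0	1.38	1.46	1.02219421690	3.136363636	7.024142453	2.6102	tabulated
Li	0	164.20	1387.00	0.06859127758	172.842105263	1473.072631713	7.1274	tabulated
Be	0	38.00	214.00	0.19759926131	63.333333333	386.249466402	5.3847	tabulated
B	0	21.00	99.50	0.30083144369	46.666666667	257.059586985	4.9603	tabulated
C	0	12.00	46.60	0.43148148148	35.294117647	177.130984377	4.6082	tabulated
N	0	7.40	24.20	0.58923788654	22.424242424	96.749442380	4.1019	tabulated
O	0	5.40	15.60	0.71330589849	18.000000000	72.175217997	3.8828	tabulated
F	0	3.80	9.52	0.87903970452	13.571428571	49.528919211	3.6238	tabulated
Ne	0	2.67	6.38	1.19326497309	5.933333333	16.434497422	2.9914	tabulated
Na	0	162.70	1556.00	0.07837421851	171.263157895	1455.157585929	7.1087	tabulated
Mg	0	71.00	627.00	0.16584011109	118.333333333	888.861772107	6.4004	tabulated
Al	0	60.00	528.00	0.19555555556	133.333333333	1042.180828055	6.6196	tabulated
Si	0	37.00	305.00	0.29705381057	100.000000000	710.163091543	6.1057	tabulated
P	0	25.00	185.00	0.39466666667	75.757575758	490.447873535	5.6544	tabulated
S	0	19.60	134.00	0.46508399278	65.333333333	402.597604382	5.4303	tabulated
Cl	0	15.00	94.60	0.56059259259	53.571428571	308.983817391	5.1467	tabulated
Ar	0	11.10	64.30	0.69583096610	24.666666667	109.859778106	4.2021	tabulated
K	0	292.90	3897.00	0.06056621014	308.315789474	3186.782713335	8.4312	tabulated
Ca	0	160.00	2221.00	0.11567708333	266.666666667	2626.131126127	8.0803	tabulated
Br	0	20.00	162.00	0.54000000000	71.428571429	453.440927161	5.5640	tabulated
Kr	0	16.80	129.60	0.61224489796	37.333333333	190.906385363	4.6764	tabulated
Sr	0	204.51	3149.00	0.10038811507	340.850000000	3642.860119285	8.6839	tabulated
Y	0	158.81	2712.00	0.14337476871	317.620000000	3315.649026803	8.5052	tabulated
Zr	0	143.47	2326.00	0.15066981339	286.940000000	2895.651037945	8.2553	tabulated
I	0	35.00	385.00	0.41904761905	125.000000000	956.250000000	6.5000	tabulated
Xe	0	27.30	285.90	0.51147875324	60.666666667	364.718904885	5.3222	tabulated
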