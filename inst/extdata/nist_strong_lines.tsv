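# Reference emission lines for LIBS ionomic profiling of fungal biomass.
# Strong persistent lines per element, air wavelengths (nm), from the NIST
# Atomic Spectra Database; relative_strength is a within-element weight used
# by the simulator (1.0 = the element's primary line). The CN violet-system
# band head (B2Sigma+ - X2Sigma+, dv=0) is represented as a single
# pseudo-line and flagged as a molecular band.
feature_label	center_wavelength	relative_strength	is_molecular_band
C	247.86	1.0	FALSE
Zn	213.86	1.0	FALSE
Zn	334.50	0.45	FALSE
Zn	481.05	0.30	FALSE
P	253.56	1.0	FALSE
P	255.33	0.80	FALSE
Mn	403.08	1.0	FALSE
Mn	257.61	0.70	FALSE
Mg	285.21	1.0	FALSE
Mg	279.55	0.90	FALSE
Mg	280.27	0.60	FALSE
Si	288.16	1.0	FALSE
Si	251.61	0.70	FALSE
Fe	371.99	1.0	FALSE
Fe	373.71	0.60	FALSE
Fe	404.58	0.40	FALSE
Ca	422.67	1.0	FALSE
Ca	393.37	0.90	FALSE
Ca	396.85	0.50	FALSE
Al	396.15	1.0	FALSE
Al	394.40	0.50	FALSE
Na	589.00	1.0	FALSE
Na	589.59	0.50	FALSE
H	656.28	1.0	FALSE
Li	670.78	1.0	FALSE
Li	610.36	0.25	FALSE
K	766.49	1.0	FALSE
K	769.90	0.60	FALSE
O	777.19	1.0	FALSE
O	844.64	0.35	FALSE
N	746.83	1.0	FALSE
N	821.63	0.60	FALSE
N	868.03	0.40	FALSE
CN	388.34	1.0	TRUE
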