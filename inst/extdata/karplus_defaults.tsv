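# Default Karplus coefficients: J = A cos^2(theta + phase) + B cos(theta + phase) + C
# Editable configuration; values are empirical parameterizations in Hz.
coupling_type	A	B	C	phase_deg
H1H2	9.67	-2.03	0.0	0
H2H3	9.67	-2.03	0.0	0
H3H4	9.67	-2.03	0.0	0
H4H5p	9.70	-1.80	0.0	-120
H4H5pp	9.70	-1.80	0.0	120
H5P	15.30	-6.10	1.60	120
H5pP	15.30	-6.10	1.60	-120
H3P	15.30	-6.10	1.60	-120
C4Pb	6.90	-3.40	0.70	0
C4Pe	6.90	-3.40	0.70	0
generic	7.00	-1.00	0.50	0
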