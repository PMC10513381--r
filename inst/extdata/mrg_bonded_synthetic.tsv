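# SYNTHETIC stand-in for the MRG-CG DNA polynomial bonded coefficients.
# U(x) = k2 x^2 + k3 x^3 + k4 x^4 with x = r - r0 (bond/fan, x0 in nm,
# k_n in kcal/mol/nm^n) or x = theta - theta0 (angle, x0 in degrees,
# k_n in kcal/mol/degree^n).  Coefficients chosen for B-DNA-like geometry
# and bending stiffness; NOT the published renormalization-group values.
term	delta	x0	k2	k3	k4
bond	NA	0.34	200	-100	800
angle	NA	180	0.0134	0	1e-06
fan	-2	1.209	1	0	2
fan	-1	1.057	2	0	4
fan	0	1	4	0	8
fan	1	1.057	2	0	4
fan	2	1.209	1	0	2
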