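# Chromophore absorption coefficients mu_a [1/cm] vs wavelength [nm].
# Literature-based defaults (synthetic compilation assembled for this package):
#   oxy_hb / deoxy_hb : whole blood at 150 g Hb / L, from tabulated molar
#                       extinction coefficients (mu_a = 2.303 * eps * 150/64500)
#   water             : pure-water absorption compilation
#   fat               : soft-tissue lipid absorption
#   melanin           : interior melanosome power law 1.70e12 * lambda^-3.48
#   baseline          : bloodless-skin baseline 0.244 + 85.3*exp(-(lambda-154)/66.2)
#   collagen          : literature-typical dry-collagen values
# Linear interpolation between rows; lookups outside [600, 1000] nm error out.
wavelength_nm	oxy_hb	deoxy_hb	water	fat	melanin	baseline	collagen
600	17.14	78.61	0.00222	0.0105	365.0	0.3452	0.20
660	1.712	17.28	0.00400	0.0083	261.0	0.2851	0.22
700	1.553	9.610	0.00624	0.0089	213.0	0.2663	0.25
750	2.774	7.526	0.02620	0.0107	167.0	0.2546	0.28
800	4.370	4.080	0.02040	0.0106	134.0	0.2494	0.30
850	5.667	3.703	0.04330	0.0119	109.0	0.2469	0.33
900	6.416	4.080	0.06790	0.0658	89.0	0.2457	0.38
940	6.502	3.714	0.26700	0.1120	76.0	0.2452	0.42
1000	6.093	3.060	0.36300	0.0426	61.4	0.2447	0.50
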