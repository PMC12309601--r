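# APPROXIMATE reconstruction of the ACE metalation titration: points were not
# tabulated at source, so these are curve points regenerated from the printed
# parameters (n = 0.90, half-saturation 2.8e-18 M, free-copper axis) and
# rounded to 3 significant figures. Tests bind to the printed parameters, not
# to these points.
ligand_concentration_M	apo_fraction
2.8e-20	0.984
4.98e-20	0.974
8.85e-20	0.957
1.57e-19	0.93
2.8e-19	0.888
4.98e-19	0.826
8.85e-19	0.738
1.57e-18	0.627
2.8e-18	0.5
4.98e-18	0.373
8.85e-18	0.262
1.57e-17	0.174
2.8e-17	0.112
4.98e-17	0.0698
8.85e-17	0.0428
1.57e-16	0.0259
2.8e-16	0.0156
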