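# APPROXIMATE reconstruction of the MAC metalation titration: points were not
# tabulated at source, so these are curve points regenerated from the printed
# parameters (n = 0.62, half-saturation 9.7e-20 M, free-copper axis) and
# rounded to 3 significant figures. Tests bind to the printed parameters, not
# to these points.
ligand_concentration_M	apo_fraction
9.7e-22	0.946
1.72e-21	0.924
3.07e-21	0.895
5.45e-21	0.856
9.7e-21	0.807
1.72e-20	0.745
3.07e-20	0.671
5.45e-20	0.588
9.7e-20	0.5
1.72e-19	0.412
3.07e-19	0.329
5.45e-19	0.255
9.7e-19	0.193
1.72e-18	0.144
3.07e-18	0.105
5.45e-18	0.076
9.7e-18	0.0544
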