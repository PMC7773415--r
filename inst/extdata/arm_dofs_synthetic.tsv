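dof	rom_min	rom_max
ra_wr_s_p	-1.5708	1.5708
ra_wr_e_f	-1.2217	1.2217
ra_cmc1_f_e	-0.2618	0.9599
ra_cmc1_a_a	-0.1745	1.0472
ra_mcp1_f_e	0	1.0472
ra_ip1_f_e	-0.2618	1.3963
ra_mcp2_f_e	-0.3491	1.5708
ra_pip2_f_e	0	1.7453
ra_dip2_f_e	0	1.3963
ra_mcp3_f_e	-0.3491	1.5708
ra_pip3_f_e	0	1.7453
ra_dip3_f_e	0	1.3963
ra_mcp4_f_e	-0.3491	1.5708
ra_pip4_f_e	0	1.7453
ra_dip4_f_e	0	1.3963
ra_mcp5_f_e	-0.3491	1.5708
ra_pip5_f_e	0	1.7453
ra_dip5_f_e	0	1.3963
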