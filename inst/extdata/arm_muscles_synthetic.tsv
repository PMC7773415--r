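muscle	category	dofs
BIC_LO	wrist_supinator	ra_wr_s_p
BIC_SH	wrist_supinator	ra_wr_s_p
SUP	wrist_supinator	ra_wr_s_p
PT	wrist_pronator	ra_wr_s_p
PQ	wrist_pronator	ra_wr_s_p
ECR_LO	wrist_extensor	ra_wr_e_f;ra_wr_s_p
ECR_BR	wrist_extensor	ra_wr_e_f;ra_wr_s_p
ECU	wrist_extensor	ra_wr_e_f;ra_wr_s_p
FCR	wrist_flexor	ra_wr_e_f;ra_wr_s_p
FCU	wrist_flexor	ra_wr_e_f;ra_wr_s_p
PL	wrist_flexor	ra_wr_e_f;ra_wr_s_p
FDS2	finger_flexor	ra_wr_e_f;ra_mcp2_f_e;ra_pip2_f_e
FDS3	finger_flexor	ra_wr_e_f;ra_mcp3_f_e;ra_pip3_f_e
FDS4	finger_flexor	ra_wr_e_f;ra_mcp4_f_e;ra_pip4_f_e
FDS5	finger_flexor	ra_wr_e_f;ra_mcp5_f_e;ra_pip5_f_e
FDP2	finger_flexor	ra_wr_e_f;ra_mcp2_f_e;ra_pip2_f_e;ra_dip2_f_e
FDP3	finger_flexor	ra_wr_e_f;ra_mcp3_f_e;ra_pip3_f_e;ra_dip3_f_e
FDP4	finger_flexor	ra_wr_e_f;ra_mcp4_f_e;ra_pip4_f_e;ra_dip4_f_e
FDP5	finger_flexor	ra_wr_e_f;ra_mcp5_f_e;ra_pip5_f_e;ra_dip5_f_e
ED2	finger_extensor	ra_wr_e_f;ra_mcp2_f_e;ra_pip2_f_e;ra_dip2_f_e
ED3	finger_extensor	ra_wr_e_f;ra_mcp3_f_e;ra_pip3_f_e;ra_dip3_f_e
ED4	finger_extensor	ra_wr_e_f;ra_mcp4_f_e;ra_pip4_f_e;ra_dip4_f_e
ED5	finger_extensor	ra_wr_e_f;ra_mcp5_f_e;ra_pip5_f_e;ra_dip5_f_e
EDM	finger_extensor	ra_wr_e_f;ra_mcp5_f_e;ra_pip5_f_e;ra_dip5_f_e
EIND	finger_extensor	ra_wr_e_f;ra_mcp2_f_e;ra_pip2_f_e;ra_dip2_f_e
APL	thumb	ra_wr_e_f;ra_wr_s_p;ra_cmc1_f_e;ra_cmc1_a_a
OP	thumb	ra_cmc1_f_e;ra_cmc1_a_a
APB	thumb	ra_cmc1_f_e;ra_cmc1_a_a;ra_mcp1_f_e
FPB	thumb	ra_cmc1_f_e;ra_cmc1_a_a;ra_mcp1_f_e
ADPT	thumb	ra_cmc1_f_e;ra_cmc1_a_a;ra_mcp1_f_e
EPB	thumb	ra_wr_e_f;ra_cmc1_f_e;ra_cmc1_a_a;ra_mcp1_f_e
EPL	thumb	ra_wr_e_f;ra_cmc1_f_e;ra_cmc1_a_a;ra_mcp1_f_e;ra_ip1_f_e
FPL	thumb	ra_wr_e_f;ra_wr_s_p;ra_cmc1_f_e;ra_cmc1_a_a;ra_mcp1_f_e;ra_ip1_f_e
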