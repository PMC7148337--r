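exchange_id	lb	ub	always_open
EX_glc__D_e	-1000	1000	FALSE
EX_o2_e	-1000	1000	FALSE
EX_nh4_e	-1000	1000	FALSE
EX_pi_e	-1000	1000	FALSE
EX_h2o_e	-1000	1000	TRUE
EX_h_e	-1000	1000	TRUE
EX_co2_e	-1000	1000	TRUE
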