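"name","F_max","l_opt","v_max","l_slack","tau_act","u0","fast_twitch","delay","n_joint","joint1","arm_type1","r0_1","theta_m1","theta_ref1","sign1","joint2","arm_type2","r0_2","theta_m2","theta_ref2","sign2"
"ILPSO",2000,0.11,12,0.1,0.01,0.01,0.5,0.005,1,0,0,0.1,0,0.3,1,0,0,0,0,0,1
"GMAX",1500,0.11,12,0.13,0.01,0.01,0.45,0.005,1,0,0,0.1,0,0.3,-1,0,0,0,0,0,1
"HAMS",3000,0.1,12,0.31,0.01,0.01,0.4,0.005,2,0,0,0.08,0,0.3,-1,1,0,0.05,0,0.3,1
"RF",1200,0.08,12,0.35,0.01,0.01,0.55,0.005,2,0,0,0.08,0,0.3,1,1,1,0.045,0.8,0.3,-1
"VAS",6000,0.08,12,0.23,0.01,0.01,0.5,0.01,1,1,1,0.06,0.8,0.3,-1,0,0,0,0,0,1
"GAS",1500,0.05,12,0.4,0.01,0.01,0.5,0.02,2,1,0,0.04,0,0.3,1,2,1,0.05,-0.15,0,-1
"SOL",4000,0.04,6,0.26,0.01,0.01,0.2,0.02,1,2,1,0.05,-0.15,0,-1,0,0,0,0,0,1
"TA",800,0.06,12,0.24,0.01,0.01,0.7,0.02,1,2,1,0.04,0.25,0,1,0,0,0,0,0,1
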