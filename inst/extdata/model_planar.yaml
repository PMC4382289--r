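m_hat: 53.5
I_hat: 3.0
d_hat: 0.35
l_hat: 0.8
m_thigh: 8.5
I_thigh: 0.15
d_thigh: 0.2
l_thigh: 0.5
m_shank: 3.5
I_shank: 0.05
d_shank: 0.2
l_shank: 0.5
m_foot: 1.25
I_foot: 0.005
foot_com:
- 0.05
- -0.03
heel_offset:
- -0.06
- -0.05
ball_offset:
- 0.13
- -0.05
sphere_radius: 0.01
m_back: 0.0
I_back: 0.0
back_dx: -0.1
gravity:
- 0.0
- -9.80665
limit_lower:
- -0.35
- 0.0
- -0.9
limit_upper:
- 2.0
- 2.5
- 0.7
limit_stiffness: 300.0
limit_damping: 30.0
fall_height: 0.7
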