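# Symmetric typical-path airway geometry (regular dichotomy), after the
# classical 23-generation morphometric model at a total lung volume of
# 4800 mL. Linear dimensions are rescaled in code to the subject's functional
# residual capacity by (FRC/4800)^(1/3). Regions: TB = conducting
# (trachea .. terminal/respiratory bronchioles), AL = alveolated acinus.
# branch_angle_deg: bifurcation angle used by the inertial-impaction kernel.
# gravity_angle_deg: tube inclination from horizontal used by the
# sedimentation kernel (90 = vertical trachea).
generation,count,diameter_cm,length_cm,branch_angle_deg,gravity_angle_deg,region
0,1,1.80,12.00,0,90,TB
1,2,1.22,4.76,33,45,TB
2,4,0.83,1.90,34,45,TB
3,8,0.56,0.76,35,45,TB
4,16,0.45,1.27,37,40,TB
5,32,0.35,1.07,39,40,TB
6,64,0.28,0.90,40,40,TB
7,128,0.23,0.76,42,40,TB
8,256,0.186,0.64,44,40,TB
9,512,0.154,0.54,45,38,TB
10,1024,0.130,0.46,45,38,TB
11,2048,0.109,0.39,45,38,TB
12,4096,0.095,0.33,45,38,TB
13,8192,0.082,0.27,45,38,TB
14,16384,0.074,0.23,45,38,TB
15,32768,0.066,0.20,45,38,TB
16,65536,0.060,0.165,45,38,TB
17,131072,0.054,0.141,45,38,AL
18,262144,0.050,0.117,45,38,AL
19,524288,0.047,0.099,45,38,AL
20,1048576,0.045,0.083,45,38,AL
21,2097152,0.043,0.070,45,38,AL
22,4194304,0.041,0.059,45,38,AL
23,8388608,0.041,0.050,45,38,AL
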