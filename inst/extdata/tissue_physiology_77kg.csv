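# Whole-body physiology for the reference subject (30-year-old male, 77 kg,
# BMI 24.9): tissue volumes and arterial blood-flow fractions of cardiac
# output, from standard compiled human physiology tables. Plasma flows are
# derived in code as fraction x plasma cardiac output. Gut and spleen drain
# into the liver (splanchnic arrangement); "rest" closes the mass balance of
# poorly characterized tissues.
tissue,volume_L,flow_frac_co
adipose,17.0,0.050
bone,7.9,0.040
brain,1.45,0.120
gut,1.65,0.150
heart,0.33,0.040
kidney,0.31,0.180
liver,1.82,0.065
muscle,29.5,0.170
skin,3.4,0.050
spleen,0.19,0.030
rest,6.8,0.105
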