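# Archival Next Generation Impactor stage calibration.
# d50_um: stage cut-off aerodynamic diameter at the 60 L/min reference flow.
# exponent: per-stage flow-scaling exponent x in d50(Q) = d50_ref * (60/Q)^x,
# from the archival full-flow-range calibration of the impactor.
stage,d50_um,exponent
1,8.06,0.54
2,4.46,0.52
3,2.82,0.50
4,1.66,0.47
5,0.94,0.53
6,0.55,0.60
7,0.34,0.67
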