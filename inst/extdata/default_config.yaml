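# Default NGV GLUT1-deficiency study configuration
label: ngv_study
seed: 1
deficiency_factor: 0.4
atp_ladder_n: 5
atp_ladder_dmax: 1.0
cv_duration: 600
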