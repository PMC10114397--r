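subject_id,phase,va_logmar,pep_h_deg,pep_v_deg,brbp_right,brbp_left,stereo_arcsec
S1,pre,1.00,1.28,,,4,400
S1,post,0.10,0.64,,8,7,200
S2,pre,0.60,1.5,,7,3,none
S2,post,0.10,0.18,,8,6,400
S3,pre,0.60,0.5,,2,8,none
S3,post,0.10,0.32,,6,8,none
S4,pre,0.80,0.58,,8,1,none
S4,post,0.20,0.36,,8,6,none
S5,pre,0.80,0.48,,6,5,none
S5,post,0.10,0.38,,8,6,none
S6,pre,0.20,0.42,,5,8,none
S6,post,0.10,0.14,,7,8,none
S7,pre,0.50,1.46,,3,4,100
S7,post,0.15,0.88,,6,4,none
S8,pre,0.40,0.28,,4,8,none
S8,post,0.10,0.1,,6,8,none
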