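code,a,e,f,p_diet
WEIRAC,4.53,16.6,3.3e-5,0.08
WEISIL,4.53,16.6,3.3e-5,0.33
OLERAN,3.46,14.54,3.83e-5,0.1
SCHDIG,3.92,60.79,1.6e-4,0.4
BEITAW,4.29,8.79,2.33e-5,0.33
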