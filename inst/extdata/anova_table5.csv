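source,df,ss_obs,ss_sim
Variety,15,75.41,85.57
Environment,7,261.73,265.27
Variety:Environment,105,50.89,63.49
Rep,1,0.02,0.27
Error,127,4.58,0.08
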