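{"b":0.65,"d":0.15,"mu_s":2e-06,"mu_p":2e-05,"tp":{"B":0.65,"D0":0.15,"k0":2.3,"a":0.2,"t0":0,"S0":0,"lambda_variant":"linear","lambda0":0,"k":0.002,"Dp":0.01,"f0":0},"dose":5,"dt":0.05,"nu_pre":0,"mutate_sensitive_during_treatment":true,".class":"mcld_parameters"}
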