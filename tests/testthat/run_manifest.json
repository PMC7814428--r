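{"command":"no-such-command","alpha0_deg":10,"spoi_deg":[20,10,0,-10],"correction_deg":[0,5,10,15,20,25,30],"n_reps":10,"sigma_point_mm":0.025,"sigma_mount_deg":0.25,"seed":1,"alpha":0.05,"versions":{"owhto":"0.1.0","R":"4.3.3"}}
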