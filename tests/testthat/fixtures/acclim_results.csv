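site,taxon,n,eligible,observed_median,p,n_resamples,seed
North,Brancher,3,FALSE,1,NA,2000,890709059
North,Encruster,13,TRUE,0,0.6145,2000,2031659428
South,Brancher,4,FALSE,-1.5,NA,2000,1950098358
South,Encruster,15,TRUE,-2,0.094,2000,512989345
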