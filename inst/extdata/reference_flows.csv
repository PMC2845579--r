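region,timepoint,state,mean_mbf,sd_mbf
targeted,baseline,rest,0.67,0.17
targeted,baseline,stress,0.83,0.16
nontargeted,baseline,rest,0.97,0.9
nontargeted,baseline,stress,2.01,0.7
targeted,followup,rest,0.75,0.3
targeted,followup,stress,1.12,0.5
nontargeted,followup,rest,1.01,0.5
nontargeted,followup,stress,2.3,0.7
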