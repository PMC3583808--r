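outcome,hsct,btict,incremental
direct_medical,83733.58,28651.11,55082.47
direct_non_medical,9877.00,29928.83,-20541.83
indirect,20389.58,15347.89,5041.69
total,114000.16,73927.83,40072.33
qalys,26.49,14.11,12.38
icer,NA,NA,3236.37
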