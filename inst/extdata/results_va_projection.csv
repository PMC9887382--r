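centre,cohort,month,n,mean_va,sd_va
MEH,matched,0,215,52.9,14.5
MEH,matched,12,215,43.6,17.8
MEH,unmatched,0,110,59.5,18.4
MEH,unmatched,12,110,41.9,12.3
UHB,matched,0,44,52.6,16.0
UHB,matched,12,44,40.6,17.0
UHB,unmatched,0,7,40.6,21.0
UHB,unmatched,12,7,29.5,8.2
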