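centre,n,month,threshold,count,source
MEH,325,0,ge70,83,results_text
MEH,325,0,ge70,77,table2
MEH,325,3,ge70,25,results_text
MEH,325,12,ge70,19,results_text
MEH,325,0,lt25,14,results_text
MEH,325,0,lt25,19,table2
MEH,325,12,lt25,46,results_text
MEH,325,0,le20,5,results_text
MEH,325,0,le20,6,table2
MEH,325,12,le20,15,results_text
UHB,51,0,ge70,5,results_text
UHB,51,0,ge70,9,table2
UHB,51,3,ge70,2,results_text
UHB,51,12,ge70,4,results_text
UHB,51,0,lt25,3,results_text
UHB,51,0,lt25,2,table2
UHB,51,12,lt25,4,results_text
UHB,51,0,le20,2,results_text
UHB,51,0,le20,2,table2
UHB,51,12,le20,3,results_text
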