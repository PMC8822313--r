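bin,t,E,rc,n_correct,n_error
"(0,40]",1,0,0,0,0
"(40,80]",2,0,0,0,0
"(80,120]",3,0,0,0,0
"(120,160]",4,0,0,0,0
"(160,200]",5,0,0,0,0
"(200,240]",6,0,0,0,0
"(240,280]",7,7,0,2,5
"(280,320]",8,13,0,10,3
"(320,360]",9,26,0,24,2
"(360,400]",10,40,0,40,0
"(400,440]",11,48,0,47,1
"(440,480]",12,37,0,37,0
"(480,520]",13,32,0,32,0
"(520,560]",14,9,0,9,0
"(560,600]",15,4,4,4,0
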