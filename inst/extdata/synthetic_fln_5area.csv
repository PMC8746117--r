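"","A1","A2","A3","A4","A5"
"A1",0,0.140150859008401,0.035153136118617,0.1765266736853,0.373278241819071
"A2",0.307632740798467,0,0.0100983238308531,0.00523045943527139,0.147484928852939
"A3",0.00102143280306052,0.262086134224788,0,0.0283162693740906,0.0301129354580341
"A4",0.00728217759801822,0.573292088383051,0.115215117427872,0,0.0036947933385601
"A5",0.41412298942491,0.0025698583375776,0.00454801595615942,0.0109913711411922,0
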