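"","A1","A2","A3","A4","A5"
"A1",0,5.59215690713338,3.8975352409858,3.95072254374498,0.697858702965787
"A2",5.59215690713338,0,6.6163814633274,7.70241390269897,5.27843870159017
"A3",3.8975352409858,6.6163814633274,0,6.52335741184865,4.38583660994979
"A4",3.95072254374498,7.70241390269897,6.52335741184865,0,4.25189282128687
"A5",0.697858702965787,5.27843870159017,4.38583660994979,4.25189282128687,0
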