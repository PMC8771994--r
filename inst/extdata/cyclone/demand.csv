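"facility","Measles vaccine","Pentavalent vaccine","Syringes 5ml","ORS sachets"
"Province A",0,0,0,0
"Center B",40,50,30,60
"Center C",25,30,20,40
"Center D",35,20,25,30
"Center E",20,25,15,35
"Center F",45,35,30,50
"Center G",15,20,10,25
"Center H",30,25,20,30
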