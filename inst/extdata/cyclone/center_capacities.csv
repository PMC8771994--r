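"facility","cold_capacity","ambient_capacity"
"Province A",2000,8000
"Center B",150,400
"Center C",90,250
"Center D",100,300
"Center E",70,200
"Center F",160,420
"Center G",60,180
"Center H",100,280
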