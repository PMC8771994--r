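"facility","Province A","Center B","Center C","Center D","Center E","Center F","Center G","Center H"
"Province A",0,41.1,55.5,75.8,78.3,92.4,91.9,108.2
"Center B",41.1,0,43.6,36.8,39.5,61.7,82.2,69.1
"Center C",55.5,43.6,0,47.3,74.1,43.6,39.5,71.8
"Center D",75.8,36.8,47.3,0,35,33.1,73.5,32.5
"Center E",78.3,39.5,74.1,35,0,67.9,106.6,53.6
"Center F",92.4,61.7,43.6,33.1,67.9,0,49.5,35
"Center G",91.9,82.2,39.5,73.5,106.6,49.5,0,84.5
"Center H",108.2,69.1,71.8,32.5,53.6,35,84.5,0
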