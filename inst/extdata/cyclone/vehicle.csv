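"vehicle","available","condition","cold_capacity","ambient_capacity","fuel_consumption","crew_size"
"Landcruiser_3PL","available","Good",350,1500,0.18,2
"New Vehicle","available","Fair",250,1000,0.15,2
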