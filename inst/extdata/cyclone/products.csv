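"product","requires_cold","unit_volume"
"Measles vaccine","yes","1.2"
"Pentavalent vaccine","yes","0.8"
"Syringes 5ml","no","2.5"
"ORS sachets","no","1"
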