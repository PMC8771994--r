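"facility","Province A","Center B","Center C","Center D","Center E","Center F","Center G","Center H"
"Province A","Fully paved","Partially paved","Fully paved","Partially paved","Dirt road (Rough)","Partially paved","Dirt road (Rough)","Partially paved"
"Center B","Partially paved","Fully paved","Fully paved","Fully paved","Fully paved","Partially paved","Partially paved","Fully paved"
"Center C","Fully paved","Fully paved","Fully paved","Partially paved","Partially paved","Partially paved","Fully paved","Fully paved"
"Center D","Partially paved","Fully paved","Partially paved","Fully paved","Fully paved","Fully paved","Fully paved","Fully paved"
"Center E","Dirt road (Rough)","Fully paved","Partially paved","Fully paved","Fully paved","Dirt road (Good Quality)","Partially paved","Dirt road (Good Quality)"
"Center F","Partially paved","Partially paved","Partially paved","Fully paved","Dirt road (Good Quality)","Fully paved","Fully paved","Fully paved"
"Center G","Dirt road (Rough)","Partially paved","Fully paved","Fully paved","Partially paved","Fully paved","Fully paved","Dirt road (Good Quality)"
"Center H","Partially paved","Fully paved","Fully paved","Fully paved","Dirt road (Good Quality)","Fully paved","Dirt road (Good Quality)","Fully paved"
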