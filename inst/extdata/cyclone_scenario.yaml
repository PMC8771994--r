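# Emergency adjustments after a cyclone: the provincial warehouse is
# damaged, so distribution moves to Center B; three facilities cannot
# store products and drop out; displaced demand concentrates at Centers
# B and F; the road between Center B and Center E is destroyed.
new_depot: Center B
zero_demand:
  - Province A
  - Center C
  - Center D
demand_multipliers:
  Center B: 2
  Center F: 2
road_blocks:
  - [Center B, Center E]
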