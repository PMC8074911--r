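oscillator_id,consumer,resource
1,phorid_fly,azteca_ant
2,orb_spider,phorid_fly
3,orb_spider,scale_hyperparasitoid
4,orb_spider,azteca_ant
5,azya_beetle,green_scale
6,coccophagus_wasp,green_scale
7,white_halo_fungus,green_scale
8,scale_hyperparasitoid,coccophagus_wasp
9,white_halo_fungus,coffee_rust
10,mycodiplosis_fly,coffee_rust
11,rust_mycoparasite,coffee_rust
12,rust_bacterium,coffee_rust
13,rust_mite,coffee_rust
14,closterocerus_wasp,coffee_leaf_miner
15,horismenus_wasp,coffee_leaf_miner
16,pheidole_ant,coffee_leaf_miner
17,cephalonomia_wasp,coffee_berry_borer
18,prorops_wasp,coffee_berry_borer
19,beauveria_fungus,coffee_berry_borer
20,pheidole_ant,coffee_berry_borer
21,phymastichus_wasp,coffee_berry_borer
22,azteca_ant,coffee_berry_borer
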