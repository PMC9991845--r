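schema_version: 1
items:
- item_id: maize_porridge_soft
  dds_group: 1
  flags:
  - starchy
  starchy_unit_g: 125.0
  kj_per_100g: 270.0
- item_id: maize_porridge_stiff
  dds_group: 1
  flags:
  - starchy
  starchy_unit_g: 60.0
  kj_per_100g: 550.0
- item_id: maize_porridge_crumbly
  dds_group: 1
  flags:
  - starchy
  starchy_unit_g: 45.0
  kj_per_100g: 700.0
- item_id: brown_bread
  dds_group: 1
  flags:
  - starchy
  starchy_unit_g: 35.0
  kj_per_100g: 1010.0
- item_id: white_bread
  dds_group: 1
  flags:
  - starchy
  starchy_unit_g: 35.0
  kj_per_100g: 1090.0
- item_id: potato
  dds_group: 1
  flags:
  - starchy
  starchy_unit_g: 100.0
  kj_per_100g: 320.0
- item_id: sweet_potato
  dds_group: 1
  flags:
  - starchy
  starchy_unit_g: 100.0
  kj_per_100g: 380.0
- item_id: cooked_pasta
  dds_group: 1
  flags:
  - starchy
  starchy_unit_g: 75.0
  kj_per_100g: 660.0
- item_id: samp
  dds_group: 1
  flags:
  - starchy
  starchy_unit_g: 75.0
  kj_per_100g: 510.0
- item_id: whole_grains
  dds_group: 1
  flags:
  - starchy
  starchy_unit_g: 75.0
  kj_per_100g: 600.0
- item_id: breakfast_cereal
  dds_group: 1
  flags:
  - starchy
  starchy_unit_g: 25.0
  kj_per_100g: 1550.0
- item_id: cooked_rice
  dds_group: 1
  flags:
  - starchy
  starchy_unit_g: 65.0
  kj_per_100g: 540.0
- item_id: spinach_morogo
  dds_group: 5
  flags:
  - fruit_veg
  kj_per_100g: 100.0
- item_id: carrots
  dds_group: 5
  flags:
  - fruit_veg
  kj_per_100g: 170.0
- item_id: pumpkin_butternut
  dds_group: 5
  flags:
  - fruit_veg
  kj_per_100g: 160.0
- item_id: mango
  dds_group: 5
  flags:
  - fruit_veg
  kj_per_100g: 250.0
- item_id: pawpaw
  dds_group: 5
  flags:
  - fruit_veg
  kj_per_100g: 180.0
- item_id: cabbage
  dds_group: 7
  flags:
  - fruit_veg
  kj_per_100g: 100.0
- item_id: tomato
  dds_group: 7
  flags:
  - fruit_veg
  kj_per_100g: 75.0
- item_id: onion
  dds_group: 7
  flags:
  - fruit_veg
  kj_per_100g: 170.0
- item_id: green_beans
  dds_group: 7
  flags:
  - fruit_veg
  kj_per_100g: 130.0
- item_id: apple
  dds_group: 8
  flags:
  - fruit_veg
  kj_per_100g: 220.0
- item_id: banana
  dds_group: 8
  flags:
  - fruit_veg
  kj_per_100g: 380.0
- item_id: orange
  dds_group: 8
  flags:
  - fruit_veg
  kj_per_100g: 200.0
- item_id: dry_beans_cooked
  dds_group: 6
  flags:
  - legume
  kj_per_100g: 530.0
- item_id: split_peas_cooked
  dds_group: 6
  flags:
  - legume
  kj_per_100g: 490.0
- item_id: lentils_cooked
  dds_group: 6
  flags:
  - legume
  kj_per_100g: 480.0
- item_id: soya_mince
  dds_group: 6
  flags:
  - legume
  kj_per_100g: 420.0
- item_id: milk
  dds_group: 3
  flags:
  - dairy_liquid
  kj_per_100g: 270.0
- item_id: maas
  dds_group: 3
  flags:
  - dairy_liquid
  kj_per_100g: 260.0
- item_id: yoghurt
  dds_group: 3
  flags:
  - dairy_liquid
  kj_per_100g: 370.0
- item_id: hard_cheese
  dds_group: 3
  flags:
  - hard_cheese
  kj_per_100g: 1680.0
- item_id: hake
  dds_group: 2
  flags:
  - fish_chicken_leanmeat
  kj_per_100g: 380.0
- item_id: tinned_pilchards
  dds_group: 2
  flags:
  - fish_chicken_leanmeat
  kj_per_100g: 600.0
- item_id: chicken_no_skin
  dds_group: 2
  flags:
  - fish_chicken_leanmeat
  kj_per_100g: 640.0
- item_id: lean_beef
  dds_group: 2
  flags:
  - fish_chicken_leanmeat
  kj_per_100g: 750.0
- item_id: eggs
  dds_group: 4
  flags:
  - egg
  kj_per_100g: 590.0
- item_id: sunflower_oil
  dds_group: 9
  flags: []
  kj_per_100g: 3700.0
- item_id: margarine_brick
  dds_group: 9
  flags: []
  kj_per_100g: 3000.0
- item_id: red_meat_fatty
  dds_group: 2
  flags: []
  kj_per_100g: 1150.0
- item_id: white_sugar
  flags: []
  kj_per_100g: 1700.0
- item_id: sweetened_drinks
  flags: []
  kj_per_100g: 180.0
- item_id: vetkoek
  flags: []
  kj_per_100g: 1450.0
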