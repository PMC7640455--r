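# 24-h recall items and the CDDS food group each one counts towards.
# Groups: 1 grains/roots/tubers, 2 vitamin-A rich, 3 other fruits and
# vegetables, 4 meat/poultry/fish/seafood, 5 eggs, 6 pulses/legumes/nuts,
# 7 milk and milk products.  No item measures foods cooked in oil or fat,
# so the attainable score is 0-7.
items:
  - item: bread_noodles
    group: 1
  - item: potato_cassava
    group: 1
  - item: eggs
    group: 5
  - item: meat
    group: 4
  - item: orange_vegetables
    group: 2
  - item: dark_green_leafy_vegetables
    group: 3
  - item: orange_fruits
    group: 2
  - item: other_fruits
    group: 3
  - item: organ_meat
    group: 4
  - item: fish_shellfish
    group: 4
  - item: beans_peas_lentils
    group: 6
  - item: milk_products
    group: 7
  - item: insects
    group: 4
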