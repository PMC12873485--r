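# Product category taxonomy.
# Foods: food groups plus processed/packaged and prepared categories;
# restaurant items always map to their own category.
# Beverages: children's-drinks style categories extended with alcoholic
# beverages and plain water; sweetened and unsweetened coffee/tea combined.
food:
  - breakfast cereals
  - packaged snacks
  - condiments and cooking staples
  - mixed dishes
  - desserts
  - fast food/restaurant
  - fruits and vegetables
  - protein
  - other food
beverage:
  - alcoholic beverages
  - energy drinks
  - coffee/tea
  - plain water
  - soda
  - fruit drinks
  - sweetened dairy drinks
  - 100% juice
  - sports drinks
  - other beverage
supplement:
  - supplement
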