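# Ordered keyword rules for product categorisation. The first rule whose
# keyword matches the product name (case-insensitive substring) wins;
# restaurant-flagged foods short-circuit to "fast food/restaurant" before
# any keyword is consulted; unmatched items fall into the type's "other"
# bucket with a warning.
food:
  - category: breakfast cereals
    keywords: [cereal, granola, muesli, oatmeal, porridge]
  - category: packaged snacks
    keywords: [chips, crisps, crackers, pretzel, popcorn, snack bar,
               granola bar, candy, chocolate bar, gummies, jerky]
  - category: condiments and cooking staples
    keywords: [ketchup, mustard, mayonnaise, sauce, dressing, seasoning,
               spice, oil, vinegar, flour, sugar, syrup, honey, butter]
  - category: desserts
    keywords: [ice cream, cake, cookie, brownie, donut, doughnut, pie,
               pastry, pudding, cupcake, cheesecake, dessert, macaron]
  - category: mixed dishes
    keywords: [lasagna, pizza, pasta, casserole, stir fry, curry, burrito,
               taco, sandwich, soup, stew, ramen, noodles, salad bowl]
  - category: fruits and vegetables
    keywords: [apple, banana, berry, berries, mango, grape, melon, orange,
               avocado, salad, vegetable, fruit, carrot, broccoli, corn]
  - category: protein
    keywords: [chicken, beef, steak, pork, fish, salmon, shrimp, egg, tofu,
               turkey, bacon, sausage]
beverage:
  - category: alcoholic beverages
    keywords: [beer, wine, vodka, whiskey, tequila, cocktail, seltzer hard,
               hard seltzer, rum, gin, champagne, liqueur, alcohol]
  - category: energy drinks
    keywords: [energy drink, energy, prime energy]
  - category: coffee/tea
    keywords: [coffee, latte, espresso, cappuccino, cold brew, cold-brew,
               tea, matcha, chai]
  - category: plain water
    keywords: [still water, sparkling water, plain water, mineral water]
  - category: soda
    keywords: [soda, cola, root beer, lemon-lime soda, soft drink]
  - category: fruit drinks
    keywords: [fruit punch, lemonade, fruit drink, juice drink, capri]
  - category: sweetened dairy drinks
    keywords: [milkshake, chocolate milk, flavored milk, smoothie, frappe]
  - category: 100% juice
    keywords: [100% juice, orange juice, apple juice, fresh juice]
  - category: sports drinks
    keywords: [sports drink, electrolyte, isotonic]
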