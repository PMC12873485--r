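# Fruit, vegetable and nut terms for the first-five-ingredients rule.
# Whole-word, case-insensitive match with simple plural handling.
terms:
  # fruit
  - apple
  - apricot
  - avocado
  - banana
  - blackberry
  - blueberry
  - cherry
  - cranberry
  - date
  - fig
  - grape
  - grapefruit
  - kiwi
  - lemon
  - lime
  - mango
  - melon
  - orange
  - papaya
  - peach
  - pear
  - pineapple
  - plum
  - pomegranate
  - raisin
  - raspberry
  - strawberry
  - watermelon
  - fruit
  # vegetables and pulses
  - artichoke
  - asparagus
  - bean
  - beet
  - broccoli
  - cabbage
  - carrot
  - cauliflower
  - celery
  - chickpea
  - corn
  - cucumber
  - eggplant
  - kale
  - lentil
  - lettuce
  - mushroom
  - onion
  - pea
  - pepper
  - potato
  - pumpkin
  - spinach
  - squash
  - tomato
  - vegetable
  - zucchini
  # nuts and seeds counted by the model
  - almond
  - cashew
  - hazelnut
  - macadamia
  - nut
  - peanut
  - pecan
  - pistachio
  - walnut
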