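# Default mapping from diet-history-questionnaire (DHQ) items to measured
# food Cd concentration sources. One entry per questionnaire item:
#   components: list of {source, weight} or {average_of: [...], weight}
#   excluded: true        marks items contributing no Cd (not detected, or
#                         measured food absent from the questionnaire)
#   mass_change_factor:   raw-equivalent mass per reported cooked/served mass
# Weights of the components of an included item must sum to 1.
# The special source RICE_INDIVIDUAL is the subject's own rice Cd
# concentration (area geometric mean when missing, x0.9 for brown rice).

rice:
  components:
    - source: RICE_INDIVIDUAL
      weight: 1.0
boiled_barley_rice:           # assumed 70% rice, 30% wheat
  components:
    - source: RICE_INDIVIDUAL
      weight: 0.7
    - source: Wheat flour
      weight: 0.3
kiritampo:
  components: [{source: Kiritampo, weight: 1.0}]
glutinous_rice:
  components: [{source: Glutinous rice, weight: 1.0}]
rice_cakes:
  components: [{source: Rice cakes, weight: 1.0}]
rice_crackers:
  components: [{source: Rice crackers, weight: 1.0}]
white_bread:
  components: [{source: White bread, weight: 1.0}]
ampan:
  components: [{source: Ampan, weight: 1.0}]
udon_and_soba:                # collective wheat/buckwheat noodle item, split in half
  components:
    - source: Udon
      weight: 0.5
    - source: Soba
      weight: 0.5
chinese_noodles:              # wheat-flour noodles, priced as udon
  components: [{source: Udon, weight: 1.0}]
spaghetti:
  components: [{source: Udon, weight: 1.0}]
butter_rolls:
  components: [{source: White bread, weight: 1.0}]
croissants:
  components: [{source: White bread, weight: 1.0}]
pizza:
  components: [{source: White bread, weight: 1.0}]
pancakes:
  components: [{source: White bread, weight: 1.0}]
okonomiyaki:
  components: [{source: White bread, weight: 1.0}]
snack_foods:
  components: [{source: Manju, weight: 1.0}]
japanese_sweets:
  components: [{source: Manju, weight: 1.0}]
cakes:
  components: [{source: Manju, weight: 1.0}]
cookies:
  components: [{source: Manju, weight: 1.0}]
doughnuts:
  components: [{source: Manju, weight: 1.0}]
sesame_seeds:
  components: [{source: Sesame seeds, weight: 1.0}]
sweet_potatoes_taro_yams:     # collective tuber item
  components:
    - average_of: [Sweet potato, Taro, Yams]
      weight: 1.0
potato:
  components: [{source: Potato, weight: 1.0}]
potato_chips:
  components: [{source: Potato chips, weight: 1.0}]
soybeans:
  components: [{source: Soybeans, weight: 1.0}]
tofu:
  components:
    - average_of: [Silken tofu, Cotton tofu]
      weight: 1.0
deep_fried_tofu:
  components: [{source: Deep-fried tofu, weight: 1.0}]
natto:
  components: [{source: Natto, weight: 1.0}]
miso:
  components: [{source: Miso, weight: 1.0}]
edamame:
  components: [{source: Edamame, weight: 1.0}]
soy_sauce:
  components: [{source: Soy sauce, weight: 1.0}]
carrot:
  components: [{source: Carrot, weight: 1.0}]
tomato:
  components: [{source: Tomato, weight: 1.0}]
squash:
  components: [{source: Squash, weight: 1.0}]
broccoli:
  components: [{source: Broccoli, weight: 1.0}]
japanese_white_radish:
  components: [{source: Japanese white radish, weight: 1.0}]
onions:
  components: [{source: Onions, weight: 1.0}]
cabbage:
  components: [{source: Cabbage, weight: 1.0}]
chinese_cabbage:
  components: [{source: Chinese cabbage, weight: 1.0}]
burdock:
  components: [{source: Burdock, weight: 1.0}]
japanese_parsley:
  components: [{source: Japanese parsley, weight: 1.0}]
eggplant:
  components: [{source: Eggplant, weight: 1.0}]
green_pepper:
  components: [{source: Green pepper, weight: 1.0}]
leafy_green_vegetables:       # collective leafy-greens item
  components:
    - average_of: [Spinach, Garland chrysanthemum, Japanese mustard spinach,
                   Bok choy, Japanese leek]
      weight: 1.0
pickled_vegetables:
  components: [{source: Pickled vegetables, weight: 1.0}]
smoked_daikon_pickles:
  components: [{source: Smoked daikon pickles, weight: 1.0}]
mushrooms:                    # half shiitake, half other mushrooms (as maitake)
  components:
    - source: Raw shiitake mushroom
      weight: 0.5
    - source: Maitake mushroom
      weight: 0.5
wakame_seaweed:
  components: [{source: Wakame seaweed (raw), weight: 1.0}]
laver:
  components: [{source: Laver, weight: 1.0}]
tuna:
  components: [{source: Tuna, weight: 1.0}]
horse_mackerel:
  components: [{source: Horse mackerel, weight: 1.0}]
mackerel:
  components: [{source: Mackerel, weight: 1.0}]
sandfish_without_eggs:
  components: [{source: Sandfish without eggs, weight: 1.0}]
sandfish_with_eggs:
  components: [{source: Sandfish with eggs, weight: 1.0}]
squid:
  components: [{source: Squid, weight: 1.0}]
salted_squid_guts:
  components: [{source: Salted squid guts, weight: 1.0}]
octopus:
  components: [{source: Octopus, weight: 1.0}]
shrimp:
  components:
    - average_of: [Prawn, Shrimp]
      weight: 1.0
fish_eggs:
  components:
    - average_of: [Cod roe, Salmon roe]
      weight: 1.0
oysters:
  components: [{source: Oysters with innards, weight: 1.0}]
other_shellfish:
  components:
    - average_of: [Scallops without innards, Japanese littleneck clam,
                   Freshwater clam]
      weight: 1.0
hampen:
  components: [{source: Hampen, weight: 1.0}]
dried_whitebait:
  components: [{source: Dried whitebait, weight: 1.0}]
broiled_eel:
  components: [{source: Broiled eel, weight: 1.0}]
liver:
  components:
    - average_of: [Beef liver, Pork liver, Chicken liver, Hinai chicken liver,
                   Innards of Hinai chicken]
      weight: 1.0
horse_meat:
  components: [{source: Horse meat, weight: 1.0}]
sausage:
  components: [{source: Sausage, weight: 1.0}]
manju:
  components: [{source: Manju, weight: 1.0}]
chocolate:
  components: [{source: Chocolate, weight: 1.0}]
curry_roux:
  components: [{source: Curry roux, weight: 1.0}]
flavor_seasonings:
  components: [{source: Flavor seasonings, weight: 1.0}]
ketchup:
  components: [{source: Ketchup, weight: 1.0}]

# Questionnaire items contributing no Cd: concentrations below detection.
animal_meat:
  excluded: true
eggs:
  excluded: true
milk:
  excluded: true
brewed_green_tea:
  excluded: true
salmon:
  excluded: true
cod:
  excluded: true
fruit:
  excluded: true
fruit_juice:
  excluded: true
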