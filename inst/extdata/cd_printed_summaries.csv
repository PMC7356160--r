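item,subgroup,area,n,mean,mean_kind,range_lo,range_hi,censored,consistent
Rice,rice_products,A,711,0.158,GM,0.02,0.971,FALSE,TRUE
Rice,rice_products,B,432,0.109,GM,0.008,0.687,FALSE,TRUE
Kiritampo,rice_products,pooled,6,0.063,AM,0.07,0.102,FALSE,FALSE
Glutinous rice,rice_products,pooled,10,0.098,AM,0.02,0.32,FALSE,TRUE
Rice cakes,rice_products,pooled,5,0.069,AM,0.017,0.182,FALSE,TRUE
Rice crackers,rice_products,pooled,4,0.091,AM,0.017,0.263,FALSE,TRUE
White bread,cereals_tubers_roots,pooled,6,0.018,AM,0.016,0.023,FALSE,TRUE
Ampan,cereals_tubers_roots,pooled,6,0.01,AM,0.01,0.014,FALSE,FALSE
Wheat flour,cereals_tubers_roots,A,3,0.021,AM,0.019,0.024,FALSE,TRUE
Udon,cereals_tubers_roots,pooled,6,0.005,AM,0.005,0.007,FALSE,TRUE
Soba,cereals_tubers_roots,pooled,6,0.019,AM,0.007,0.034,FALSE,TRUE
Sesame seeds,cereals_tubers_roots,pooled,6,0.055,AM,0.021,0.11,FALSE,TRUE
Sweet potato,cereals_tubers_roots,pooled,6,0.008,AM,0.005,0.016,FALSE,TRUE
Potato,cereals_tubers_roots,pooled,6,0.034,AM,0.005,0.098,FALSE,TRUE
Taro,cereals_tubers_roots,pooled,6,0.289,AM,0.036,0.795,FALSE,TRUE
Yams,cereals_tubers_roots,pooled,7,0.061,AM,0.005,0.167,FALSE,TRUE
Potato chips,cereals_tubers_roots,A,3,0.059,AM,0.029,0.114,FALSE,TRUE
Soybeans,soybeans,pooled,4,0.115,AM,0.05,0.25,FALSE,TRUE
Silken tofu,soybeans,pooled,5,0.015,AM,0.009,0.028,FALSE,TRUE
Cotton tofu,soybeans,pooled,6,0.027,AM,0.013,0.052,FALSE,TRUE
Deep-fried tofu,soybeans,pooled,6,0.051,AM,0.033,0.083,FALSE,TRUE
Natto,soybeans,pooled,6,0.028,AM,0.011,0.055,FALSE,TRUE
Miso,soybeans,pooled,6,0.123,AM,0.026,0.259,FALSE,TRUE
Edamame,soybeans,pooled,6,0.155,AM,0.085,0.293,FALSE,TRUE
Soy sauce,soybeans,pooled,4,0.019,AM,0.015,0.026,FALSE,TRUE
Carrot,vegetables,pooled,6,0.047,AM,0.013,0.107,FALSE,TRUE
Spinach,vegetables,pooled,6,0.064,AM,0.03,0.122,FALSE,TRUE
Tomato,vegetables,pooled,5,0.012,AM,0.005,0.022,FALSE,TRUE
Squash,vegetables,pooled,6,0.016,AM,0.008,0.024,FALSE,TRUE
Broccoli,vegetables,pooled,6,0.012,AM,0.005,0.027,FALSE,TRUE
Japanese white radish,vegetables,pooled,6,0.009,AM,0.005,0.023,FALSE,TRUE
Onions,vegetables,pooled,5,0.016,AM,0.005,0.031,FALSE,TRUE
Cabbage,vegetables,pooled,6,0.008,AM,0.006,0.011,FALSE,TRUE
Chinese cabbage,vegetables,pooled,6,0.02,AM,0.011,0.038,FALSE,TRUE
Burdock,vegetables,pooled,6,0.063,AM,0.017,0.212,FALSE,TRUE
Japanese parsley,vegetables,pooled,6,0.01,AM,0.005,0.019,FALSE,TRUE
Eggplant,vegetables,pooled,6,0.017,AM,0.005,0.028,FALSE,TRUE
Garland chrysanthemum,vegetables,pooled,5,0.074,AM,0.006,0.244,FALSE,TRUE
Japanese mustard spinach,vegetables,pooled,5,0.065,AM,0.009,0.23,FALSE,TRUE
Bok choy,vegetables,pooled,5,0.029,AM,0.01,0.101,FALSE,TRUE
Green pepper,vegetables,pooled,5,0.006,AM,0.005,0.009,FALSE,TRUE
Garlic,vegetables,pooled,6,0.051,AM,0.01,0.142,FALSE,TRUE
Okra,vegetables,pooled,3,0.023,AM,0.012,0.043,FALSE,TRUE
Belvedere fruit,vegetables,pooled,6,0.069,AM,0.041,0.095,FALSE,TRUE
Japanese leek,vegetables,A,3,0.032,AM,0.005,0.083,FALSE,TRUE
Pickled vegetables,vegetables,pooled,10,0.022,AM,0.009,0.095,FALSE,TRUE
Smoked daikon pickles,vegetables,pooled,6,0.024,AM,0.017,0.035,FALSE,TRUE
Raw shiitake mushroom,mushrooms,pooled,7,0.374,AM,0.065,0.527,FALSE,TRUE
Maitake mushroom,mushrooms,pooled,6,0.043,AM,0.023,0.108,FALSE,TRUE
Wakame seaweed (raw),seaweed,pooled,6,0.253,AM,0.069,0.544,FALSE,TRUE
Wakame seaweed (dried),seaweed,A,3,4.64,AM,4.11,5.06,FALSE,TRUE
Kelp,seaweed,pooled,6,0.682,AM,0.119,1.78,FALSE,TRUE
Laver,seaweed,pooled,4,0.413,AM,0.209,0.66,FALSE,TRUE
Hijiki seaweed,seaweed,pooled,5,1.066,AM,0.693,1.53,FALSE,TRUE
Agar-agar,seaweed,A,3,0.024,AM,0.014,0.033,FALSE,TRUE
Mozuku seaweed,seaweed,pooled,6,0.006,AM,0.005,0.01,FALSE,TRUE
Salmon,fish_shellfish,pooled,6,NA,AM,NA,NA,TRUE,TRUE
Tuna,fish_shellfish,pooled,6,0.009,AM,0.005,0.013,FALSE,TRUE
Cod,fish_shellfish,pooled,6,NA,AM,NA,NA,TRUE,TRUE
Horse mackerel,fish_shellfish,pooled,6,0.012,AM,0.007,0.015,FALSE,TRUE
Mackerel,fish_shellfish,pooled,6,0.012,AM,0.005,0.018,FALSE,TRUE
Sandfish without eggs,fish_shellfish,pooled,6,0.012,AM,0.009,0.017,FALSE,TRUE
Sandfish with eggs,fish_shellfish,pooled,6,0.014,AM,0.01,0.018,FALSE,TRUE
Squid,fish_shellfish,pooled,6,0.032,AM,0.018,0.081,FALSE,TRUE
Salted squid guts,fish_shellfish,pooled,5,2.36,AM,0.978,6.57,FALSE,TRUE
Octopus,fish_shellfish,pooled,6,0.007,AM,0.005,0.011,FALSE,TRUE
Prawn,fish_shellfish,pooled,7,0.055,AM,0.005,0.17,FALSE,TRUE
Shrimp,fish_shellfish,B,2,0.022,AM,0.009,0.035,FALSE,TRUE
Cod roe,fish_shellfish,pooled,6,0.008,AM,0.005,0.015,FALSE,TRUE
Salmon roe,fish_shellfish,pooled,3,NA,AM,NA,NA,TRUE,TRUE
Scallops without innards,fish_shellfish,pooled,5,0.0408,AM,0.012,0.103,FALSE,TRUE
Scallops with innards,fish_shellfish,pooled,5,3.635,AM,0.684,5.54,FALSE,TRUE
Oysters with innards,fish_shellfish,pooled,6,0.68,AM,0.486,1.03,FALSE,TRUE
Japanese littleneck clam,fish_shellfish,pooled,4,0.16,AM,0.028,0.305,FALSE,TRUE
Freshwater clam,fish_shellfish,pooled,4,0.375,AM,0.235,0.55,FALSE,TRUE
Hampen,fish_shellfish,pooled,6,0.005,AM,0.005,0.006,FALSE,TRUE
Dried whitebait,fish_shellfish,pooled,6,0.01,AM,0.005,0.02,FALSE,TRUE
Broiled eel,fish_shellfish,pooled,6,0.008,AM,0.005,0.011,FALSE,TRUE
Beef,livestock,pooled,6,NA,AM,NA,NA,TRUE,TRUE
Pork,livestock,pooled,5,NA,AM,NA,NA,TRUE,TRUE
Chicken,livestock,pooled,4,NA,AM,NA,NA,TRUE,TRUE
Hinai chicken,livestock,pooled,5,NA,AM,NA,NA,TRUE,TRUE
Horse meat,livestock,pooled,3,0.006,AM,0.005,0.007,FALSE,TRUE
Beef liver,livestock,A,1,0.021,AM,NA,NA,FALSE,TRUE
Pork liver,livestock,pooled,4,0.024,AM,0.016,0.028,FALSE,TRUE
Chicken liver,livestock,pooled,5,0.015,AM,0.01,0.022,FALSE,TRUE
Hinai chicken liver,livestock,A,2,0.039,AM,0.033,0.044,FALSE,TRUE
Innards of Hinai chicken,livestock,pooled,6,0.021,AM,0.008,0.066,FALSE,TRUE
Sausage,livestock,pooled,3,0.006,AM,0.005,0.008,FALSE,TRUE
Egg,livestock,pooled,6,NA,AM,NA,NA,TRUE,TRUE
Milk,livestock,pooled,6,NA,AM,NA,NA,TRUE,TRUE
Apple,fruit,pooled,6,NA,AM,NA,NA,TRUE,TRUE
Apple juice,fruit,pooled,6,NA,AM,NA,NA,TRUE,TRUE
Kiwi fruit,fruit,pooled,5,NA,AM,NA,NA,TRUE,TRUE
Manju,others,pooled,10,0.022,AM,0.01,0.127,FALSE,TRUE
Chocolate,others,A,3,0.042,AM,0.03,0.084,FALSE,FALSE
Curry roux,others,A,3,0.015,AM,0.012,0.018,FALSE,TRUE
Flavor seasonings,others,A,1,0.025,AM,NA,NA,FALSE,TRUE
Ketchup,others,pooled,3,0.016,AM,0.016,0.017,FALSE,TRUE
Japanese green tea leaves,others,A,3,0.026,AM,0.009,0.049,FALSE,TRUE
Nutritional supplement drink,others,A,3,NA,AM,NA,NA,TRUE,TRUE
Well water,others,A,7,NA,AM,NA,NA,TRUE,TRUE
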