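[
  {"fdcId": 100101, "description": "Blueberries, raw", "dataType": "SR Legacy",
   "nutrients": {"protein": 0.74, "fat": 0.33, "carbohydrate": 14.49, "fiber": 2.4}},
  {"fdcId": 100102, "description": "Blueberries, wild, raw", "dataType": "Foundation",
   "nutrients": {"protein": 0.62, "fat": 0.41, "carbohydrate": 12.15, "fiber": 2.8}},
  {"fdcId": 100103, "description": "Blueberries, canned in syrup", "dataType": "FNDDS",
   "nutrients": {"protein": 0.65, "fat": 0.33, "carbohydrate": 22.06, "fiber": 1.9}},
  {"fdcId": 100104, "description": "Blueberries, dried, brand Z", "dataType": "Branded",
   "nutrients": {"protein": 2.5, "fat": 1.7, "carbohydrate": 80.0, "fiber": 7.5}},
  {"fdcId": 100201, "description": "Chicken, breast, meat only, raw", "dataType": "SR Legacy",
   "nutrients": {"protein": 22.5, "fat": 2.62, "carbohydrate": 0.0, "fiber": 0.0}},
  {"fdcId": 100202, "description": "Oil, olive, extra virgin", "dataType": "Foundation",
   "nutrients": {"protein": 0.0, "fat": 100.0, "carbohydrate": 0.0, "fiber": 0.0}},
  {"fdcId": 100203, "description": "Mushrooms, white, raw", "dataType": "SR Legacy",
   "nutrients": {"protein": 3.09, "fat": 0.34, "carbohydrate": 3.26, "fiber": 1.0}},
  {"fdcId": 100204, "description": "Wine, marsala, cooking", "dataType": "Experimental",
   "nutrients": {"protein": 0.0, "fat": 0.0, "carbohydrate": 11.0, "fiber": 0.0}}
]
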