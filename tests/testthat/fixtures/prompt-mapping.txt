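You are tasked with matching a given ingredient <food_item> to the most appropriate one from the following list of ingredients: <list_of_food_items>. Each ingredient possesses unique characteristics that influence its compatibility with others. Your objective is to identify which ingredient from the list best complements the given one, considering factors such as flavor profile, cooking methods, and culinary traditions. Return only the ‘fdcId’ value of the best match encapsulated in dollar signs (e.g., $21341$). Do not include any comments.
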