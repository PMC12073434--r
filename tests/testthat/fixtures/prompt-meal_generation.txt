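Create a detailed one-day <INPUT_meal_type> plan. Ensure the meal plan includes precise portion sizes, specific quantities or weights of individual ingredients, and diverse cooking methods. Include compound ingredients like Chicken Cacciatore, Vegetable Ratatouille, or similar. However, avoid including ingredients included in the following list: <INPUT_list>, Structure the results in a formatted HTML format similar to the provided example: <INPUT_html_format>.
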