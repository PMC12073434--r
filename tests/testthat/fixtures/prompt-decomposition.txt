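Analyze the meal plan provided in an HTML table (enclosed within <table> and </table> tags): <INPUT_meal_plan>. Identify compound ingredients listed under the ‘Ingredient’ column that consist of multiple basic ingredients. Use the ‘Ingredient Details’ column for additional information. For each identified compound ingredient, report the names of these items along with their specific ingredients and estimated quantities based on the ‘Portion Size (g, dL)’ column, formatted in a dictionary of dictionaries. Ensure all ingredients are specific (e.g., ‘carrots’, ‘spinach’, etc., instead of ‘vegetables’). If items can be further broken down, do it. Example format: ‘Complex Food Item 1’: ‘Ingredient 1’: ‘50 g’, ‘Ingredient 2’: ‘100 g’, “Complex Food Item 2”: ‘Ingredient 1’: ‘200 g’, ‘Ingredient 2’: ‘150 g’. Return only the formatted dictionary encapsulated by dollar signs ($Content$). Dictionary should not contain any comments. If no complex food items meeting the criteria are identified, return an empty dictionary. Ensure that the quantities of each ingredient accurately reflect the specified portion size within each compound ingredient as detailed in the meal plan. For ingredients where the exact quantity cannot be determined, provide a reasonable estimate instead of leaving it unspecified.
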