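name,klass,direction,rule
fiber,dietary,antioxidant,gender_tertile
total_fat,dietary,pro-oxidant,gender_tertile
carotene,dietary,antioxidant,gender_tertile
riboflavin,dietary,antioxidant,gender_tertile
niacin,dietary,antioxidant,gender_tertile
vitamin_b6,dietary,antioxidant,gender_tertile
total_folate,dietary,antioxidant,gender_tertile
vitamin_b12,dietary,antioxidant,gender_tertile
vitamin_c,dietary,antioxidant,gender_tertile
vitamin_e,dietary,antioxidant,gender_tertile
calcium,dietary,antioxidant,gender_tertile
magnesium,dietary,antioxidant,gender_tertile
iron,dietary,pro-oxidant,gender_tertile
zinc,dietary,antioxidant,gender_tertile
copper,dietary,antioxidant,gender_tertile
selenium,dietary,antioxidant,gender_tertile
bmi,lifestyle,pro-oxidant,gender_tertile
cotinine,lifestyle,pro-oxidant,gender_tertile
pa,lifestyle,antioxidant,met_then_tertile
alcohol,lifestyle,pro-oxidant,alcohol_category
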