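variable,category,adherent,non_adherent
age,<=12,40,56
age,13-17,10,20
age,>=18,23,56
gender,Female,22,40
gender,Male,51,92
distance_km,<=10,56,80
distance_km,>10,17,52
cost_income_pct,<30,37,70
cost_income_pct,30-50,32,45
cost_income_pct,>50,4,17
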