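{"note":"synthetic fixture generated by simulate_records(sim_config(n_fields=80, years=2001:2006, n_records=220, master_seed=3))","truth":[{"model":1,"label":"alfalfa vs cotton","true_value":-80},{"model":1,"label":"barley vs cotton","true_value":10},{"model":1,"label":"carrots vs cotton","true_value":20},{"model":1,"label":"corn vs cotton","true_value":-60},{"model":1,"label":"garbanzo vs cotton","true_value":0},{"model":1,"label":"garlic vs cotton","true_value":128},{"model":1,"label":"lettuce vs cotton","true_value":30},{"model":1,"label":"melons vs cotton","true_value":440},{"model":1,"label":"onions vs cotton","true_value":-40},{"model":1,"label":"potatoes vs cotton","true_value":15},{"model":1,"label":"safflower vs cotton","true_value":-110},{"model":1,"label":"sugarbeets vs cotton","true_value":-100},{"model":1,"label":"tomatoes vs cotton","true_value":118},{"model":1,"label":"wheat vs cotton","true_value":40},{"model":1,"label":"upland vs pima","true_value":160},{"model":2,"label":"alfalfa vs cotton","true_value":0.45},{"model":2,"label":"barley vs cotton","true_value":0.05},{"model":2,"label":"carrots vs cotton","true_value":0},{"model":2,"label":"corn vs cotton","true_value":0.7},{"model":2,"label":"garbanzo vs cotton","true_value":0.1},{"model":2,"label":"garlic vs cotton","true_value":0.28},{"model":2,"label":"lettuce vs cotton","true_value":-0.05},{"model":2,"label":"melons vs cotton","true_value":-0.15},{"model":2,"label":"onions vs cotton","true_value":0.4},{"model":2,"label":"potatoes vs cotton","true_value":0.05},{"model":2,"label":"safflower vs cotton","true_value":0.45},{"model":2,"label":"sugarbeets vs cotton","true_value":0.35},{"model":2,"label":"tomatoes vs cotton","true_value":-0.2},{"model":2,"label":"wheat vs cotton","true_value":0.08},{"model":4,"label":"per consecutive cotton year","true_value":-40},{"model":5,"label":"per consecutive cotton year","true_value":0.037}]}
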