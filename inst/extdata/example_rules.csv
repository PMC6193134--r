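"kind","pattern","agent","pf","priority"
"identification_string","clavulanate-amoxicillin","clavulanate-amoxicillin","antibiotic",1
"identification_string","ampicillin","ampicillin","antibiotic",2
"identification_string","amoxicillin","amoxicillin","antibiotic",3
"identification_string","enrofloxacin","enrofloxacin","antibiotic",4
"identification_string","ciprofloxacin","ciprofloxacin","antibiotic",5
"identification_string","ofloxacin","ofloxacin","antibiotic",6
"identification_string","cefovecin","cefovecin","antibiotic",7
"identification_string","ceftriaxone","ceftriaxone","antibiotic",8
"identification_string","cephalexin","cephalexin","antibiotic",9
"identification_string","carnidazole","carnidazole","antibiotic",10
"identification_string","metronidazole","metronidazole","antibiotic",11
"identification_string","tinidazole","tinidazole","antibiotic",12
"identification_string","doxycycline","doxycycline","antibiotic",13
"identification_string","minocycline","minocycline","antibiotic",14
"identification_string","oxytetracycline","oxytetracycline","antibiotic",15
"identification_string","trimethoprim-sulfadiazine","trimethoprim-sulfadiazine","antibiotic",16
"identification_string","co-trimoxazole","co-trimoxazole","antibiotic",17
"identification_string","sulfadiazine","sulfadiazine","antibiotic",18
"identification_string","milbemycin-oxime","milbemycin-oxime","endectocide",73
"identification_string","moxidectin","moxidectin","endectocide",74
"identification_string","milbemycin","milbemycin","endectocide",75
"identification_string","selamectin","selamectin","endectocide",76
"identification_string","doramectin","doramectin","endectocide",77
"identification_string","ivermectin","ivermectin","endectocide",78
"identification_string","co-amox","amoxicillin","antibiotic",95
"identification_string","vaccine","unresolved","vaccine",96
"identification_string","vacc","unresolved","vaccine",97
"identification_string","booster","unresolved","vaccine",98
"identification_string","euthanasia","unresolved","euthanasia",99
"identification_string","pentoject","unresolved","euthanasia",100
"identification_string","pentobarbitone","unresolved","euthanasia",101
"exclusion_pattern","\btests?\b",,,1
"exclusion_pattern","syringe",,,2
"exclusion_pattern","refund",,,3
"exclusion_pattern","lab profile",,,4
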