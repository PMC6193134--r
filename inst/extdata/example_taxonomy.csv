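"agent","pc","pf","authorisation"
"clavulanate-amoxicillin","aminopenicillin","antibiotic","veterinary"
"ampicillin","aminopenicillin","antibiotic","human"
"amoxicillin","aminopenicillin","antibiotic","generic"
"enrofloxacin","fluoroquinolone","antibiotic","veterinary"
"ciprofloxacin","fluoroquinolone","antibiotic","human"
"ofloxacin","fluoroquinolone","antibiotic","generic"
"cefovecin","cephalosporin","antibiotic","veterinary"
"ceftriaxone","cephalosporin","antibiotic","human"
"cephalexin","cephalosporin","antibiotic","generic"
"carnidazole","nitroimidazole","antibiotic","veterinary"
"metronidazole","nitroimidazole","antibiotic","human"
"tinidazole","nitroimidazole","antibiotic","generic"
"doxycycline","tetracycline","antibiotic","veterinary"
"minocycline","tetracycline","antibiotic","human"
"oxytetracycline","tetracycline","antibiotic","generic"
"trimethoprim-sulfadiazine","trimethoprim sulfonamide","antibiotic","veterinary"
"co-trimoxazole","trimethoprim sulfonamide","antibiotic","human"
"sulfadiazine","trimethoprim sulfonamide","antibiotic","generic"
"milbemycin-oxime","milbemycin","endectocide","veterinary"
"moxidectin","milbemycin","endectocide","human"
"milbemycin","milbemycin","endectocide","generic"
"selamectin","avermectin","endectocide","veterinary"
"doramectin","avermectin","endectocide","human"
"ivermectin","avermectin","endectocide","generic"
"unresolved",,"vaccine",
"unresolved",,"euthanasia",
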