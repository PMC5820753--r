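[
  {"rule_id": "acidic_secondary_amide", "smarts": "[CX3](=O)[NX3H1]",
   "type_label": "acidic_secondary_amide", "delocalizing": true},
  {"rule_id": "primary_amide", "smarts": "[CX3](=O)[NX3H2]",
   "type_label": "primary_amide", "delocalizing": true},
  {"rule_id": "carboxylic_acid", "smarts": "[CX3](=O)[OX2H1]",
   "type_label": "carboxylic_acid", "delocalizing": true},
  {"rule_id": "carboxylate", "smarts": "[CX3](=O)[OX1-]",
   "type_label": "carboxylic_acid", "delocalizing": true},
  {"rule_id": "ester", "smarts": "[CX3](=O)[OX2H0]",
   "type_label": "ester", "delocalizing": true},
  {"rule_id": "imide", "smarts": "[NX3]([CX3]=O)[CX3]=O",
   "type_label": "imide", "delocalizing": false},
  {"rule_id": "aminothiooxo_imide", "smarts": "[NX3H0][CX3](=S)[NX3]",
   "type_label": "aminothiooxo_imide", "delocalizing": false},
  {"rule_id": "reversed_secondary_thioamide", "smarts": "[NX3H1][CX3]=S",
   "type_label": "reversed_secondary_thioamide", "delocalizing": false},
  {"rule_id": "reversed_secondary_amide", "smarts": "[NX3H1][CX3]=O",
   "type_label": "reversed_secondary_amide", "delocalizing": false},
  {"rule_id": "ketone", "smarts": "[CX3H0](=O)([#6])[#6]",
   "type_label": "ketone", "delocalizing": true},
  {"rule_id": "five_membered_aromatic", "smarts": "[a;r5]",
   "type_label": "five_membered_aromatic", "delocalizing": true},
  {"rule_id": "phenyl", "smarts": "c1ccccc1",
   "type_label": "phenyl", "delocalizing": true},
  {"rule_id": "thioether", "smarts": "[SX2H0]([#6])[#6]",
   "type_label": "thioether", "delocalizing": false},
  {"rule_id": "dialkyl_tertiary_amine", "smarts": "[NX3H0]([CX4])([CX4])[CX4]",
   "type_label": "dialkyl_tertiary_amine", "delocalizing": false},
  {"rule_id": "primary_amine", "smarts": "[NX3H2][CX4]",
   "type_label": "primary_amine", "delocalizing": false},
  {"rule_id": "alkyl", "smarts": "[CX4]", "veto_smarts": "[CX4][!#6]",
   "type_label": "alkyl", "delocalizing": false}
]
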