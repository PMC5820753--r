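type_label,ddg_kcal_mol,delocalizing,provenance
alkyl,-2.0,FALSE,provisional
phenyl,-14.0,TRUE,provisional
ester,-17.0,TRUE,provisional
reversed_secondary_amide,-8.0,FALSE,provisional
acidic_secondary_amide,-16.0,TRUE,provisional
primary_amide,-14.0,TRUE,provisional
five_membered_aromatic,-13.0,TRUE,provisional
ketone,-19.0,TRUE,provisional
carboxylic_acid,-12.0,TRUE,provisional
thioether,-7.0,FALSE,provisional
imide,-12.0,FALSE,provisional
dialkyl_tertiary_amine,-3.0,FALSE,provisional
primary_amine,-3.0,FALSE,provisional
reversed_secondary_thioamide,-10.0,FALSE,provisional
aminothiooxo_imide,-11.0,FALSE,provisional
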