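item,count,denominator
total,62,total
malignant,11,total
benign,51,total
type1,38,total
type2,12,total
type3,6,total
type4,5,total
malignant_type34,9,malignant
benign_type12,46,benign
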