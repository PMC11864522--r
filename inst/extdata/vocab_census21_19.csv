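code,label,harmonized18,code5,special
WHITE_BRITISH,"White: English, Welsh, Scottish, Northern Irish or British",WHITE_BRITISH,WHITE,FALSE
WHITE_IRISH,White: Irish,WHITE_IRISH,WHITE,FALSE
GYPSY_IRISH_TRAVELLER,White: Gypsy or Irish Traveller,GYPSY_IRISH_TRAVELLER,WHITE,FALSE
ROMA,White: Roma,NONE,WHITE,FALSE
WHITE_OTHER,White: Any other White background,WHITE_OTHER,WHITE,FALSE
MIXED_WHITE_BLACK_CARIBBEAN,Mixed: White and Black Caribbean,MIXED_WHITE_BLACK_CARIBBEAN,MIXED,FALSE
MIXED_WHITE_BLACK_AFRICAN,Mixed: White and Black African,MIXED_WHITE_BLACK_AFRICAN,MIXED,FALSE
MIXED_WHITE_ASIAN,Mixed: White and Asian,MIXED_WHITE_ASIAN,MIXED,FALSE
MIXED_OTHER,Mixed: Any other Mixed or multiple background,MIXED_OTHER,MIXED,FALSE
INDIAN,Asian: Indian,INDIAN,ASIAN,FALSE
PAKISTANI,Asian: Pakistani,PAKISTANI,ASIAN,FALSE
BANGLADESHI,Asian: Bangladeshi,BANGLADESHI,ASIAN,FALSE
CHINESE,Asian: Chinese,CHINESE,ASIAN,FALSE
ASIAN_OTHER,Asian: Any other Asian background,ASIAN_OTHER,ASIAN,FALSE
BLACK_AFRICAN,"Black: African",BLACK_AFRICAN,BLACK,FALSE
BLACK_CARIBBEAN,"Black: Caribbean",BLACK_CARIBBEAN,BLACK,FALSE
BLACK_OTHER,"Black: Any other Black, Black British or Caribbean background",BLACK_OTHER,BLACK,FALSE
ARAB,Other: Arab,ARAB,OTHER,FALSE
ANY_OTHER,Other: Any other ethnic group,ANY_OTHER,OTHER,FALSE
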