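code,label,harmonized18,code5,special
WHITE_BRITISH,White - British,WHITE_BRITISH,WHITE,FALSE
WHITE_IRISH,White - Irish,WHITE_IRISH,WHITE,FALSE
GYPSY_IRISH_TRAVELLER,White - Gypsy or Irish Traveller,GYPSY_IRISH_TRAVELLER,WHITE,FALSE
WHITE_OTHER,White - Any other White background,WHITE_OTHER,WHITE,FALSE
MIXED_WHITE_BLACK_CARIBBEAN,Mixed - White and Black Caribbean,MIXED_WHITE_BLACK_CARIBBEAN,MIXED,FALSE
MIXED_WHITE_BLACK_AFRICAN,Mixed - White and Black African,MIXED_WHITE_BLACK_AFRICAN,MIXED,FALSE
MIXED_WHITE_ASIAN,Mixed - White and Asian,MIXED_WHITE_ASIAN,MIXED,FALSE
MIXED_OTHER,Mixed - Any other mixed background,MIXED_OTHER,MIXED,FALSE
INDIAN,Asian or Asian British - Indian,INDIAN,ASIAN,FALSE
PAKISTANI,Asian or Asian British - Pakistani,PAKISTANI,ASIAN,FALSE
BANGLADESHI,Asian or Asian British - Bangladeshi,BANGLADESHI,ASIAN,FALSE
ASIAN_OTHER,Asian or Asian British - Any other Asian background,ASIAN_OTHER,ASIAN,FALSE
BLACK_AFRICAN,Black or Black British - African,BLACK_AFRICAN,BLACK,FALSE
BLACK_CARIBBEAN,Black or Black British - Caribbean,BLACK_CARIBBEAN,BLACK,FALSE
BLACK_OTHER,Black or Black British - Any other Black background,BLACK_OTHER,BLACK,FALSE
CHINESE,Other ethnic groups - Chinese,CHINESE,ASIAN,FALSE
ARAB,Other ethnic groups - Arab,ARAB,OTHER,FALSE
ANY_OTHER,Other ethnic groups - Any other ethnic group,ANY_OTHER,OTHER,FALSE
NOT_STATED,Not stated,,,TRUE
NOT_KNOWN,Not known,,,TRUE
UNRESOLVED,Unresolved (derived),,,TRUE
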