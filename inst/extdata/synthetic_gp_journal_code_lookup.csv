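source_code,category
ETH-1001-A,WHITE_BRITISH
ETH-1001-B,WHITE_BRITISH
ETH-1002-A,WHITE_IRISH
ETH-1002-B,WHITE_IRISH
ETH-1003-A,GYPSY_IRISH_TRAVELLER
ETH-1003-B,GYPSY_IRISH_TRAVELLER
ETH-1004-A,WHITE_OTHER
ETH-1004-B,WHITE_OTHER
ETH-1005-A,MIXED_WHITE_BLACK_CARIBBEAN
ETH-1005-B,MIXED_WHITE_BLACK_CARIBBEAN
ETH-1006-A,MIXED_WHITE_BLACK_AFRICAN
ETH-1006-B,MIXED_WHITE_BLACK_AFRICAN
ETH-1007-A,MIXED_WHITE_ASIAN
ETH-1007-B,MIXED_WHITE_ASIAN
ETH-1008-A,MIXED_OTHER
ETH-1008-B,MIXED_OTHER
ETH-1009-A,INDIAN
ETH-1009-B,INDIAN
ETH-1010-A,PAKISTANI
ETH-1010-B,PAKISTANI
ETH-1011-A,BANGLADESHI
ETH-1011-B,BANGLADESHI
ETH-1012-A,ASIAN_OTHER
ETH-1012-B,ASIAN_OTHER
ETH-1013-A,BLACK_AFRICAN
ETH-1013-B,BLACK_AFRICAN
ETH-1014-A,BLACK_CARIBBEAN
ETH-1014-B,BLACK_CARIBBEAN
ETH-1015-A,BLACK_OTHER
ETH-1015-B,BLACK_OTHER
ETH-1016-A,CHINESE
ETH-1016-B,CHINESE
ETH-1017-A,ARAB
ETH-1017-B,ARAB
ETH-1018-A,ANY_OTHER
ETH-1018-B,ANY_OTHER
ETH-1019-A,NOT_STATED
ETH-1020-A,NOT_KNOWN
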