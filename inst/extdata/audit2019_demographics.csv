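variable,category,accurate,unbilled
Sex,Male,10739,5385
Sex,Female,13882,4976
Race / Ethnicity,Asian/Pacific Islander,2406,1004
Race / Ethnicity,Black,2319,1099
Race / Ethnicity,Caucasian-Hispanic,1824,847
Race / Ethnicity,Caucasian-Non-Hispanic,12824,5041
Race / Ethnicity,Other-Hispanic,3095,1496
Race / Ethnicity,Other-Non-Hispanic,2057,831
Payor Group,Medi-Cal,3329,1570
Payor Group,Medicare,8689,4709
Payor Group,Private,12603,4082
Age Group,18-35 (young adult),5703,1577
Age Group,36-64 (middle age),9945,4300
Age Group,65-78 (aged),5432,2816
Age Group,79+ (old),2534,1199
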