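disease_name,detected,missing_icd,drg_inadequate,not_sensitive
Acidemia,2453,1551,73,2055
Acute MI,32,4,8,2010
Bacteremia,774,195,11,1093
Chronic CHF,1363,293,33,4374
Chronic Kidney Disease,4325,1061,90,3915
Inpatient Death,946,,23,
Delirium,710,570,14,644
Extremes of BMI,3931,1840,398,1087
Altered Mental Status,3457,1715,633,3420
End Stage Renal Disease,539,86,15,2805
HIV,299,21,10,65
Hyponatremia,9772,6091,431,196
Myocardial Injury,2631,977,92,5321
Acute Pancreatitis,225,45,69,277
Blood Loss Anemia,1138,304,61,4016
Respiratory Failure,854,33,29,4580
Severe Malnutrition,794,460,157,1775
Transplant,2801,112,50,594
UTI,2065,600,52,1716
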