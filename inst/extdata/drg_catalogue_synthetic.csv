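drg_code,description,rwf
101,PLEURAL EFFUSION WITH MCC,1.6215
102,PLEURAL EFFUSION WITH CC,1.1872
103,PLEURAL EFFUSION WITHOUT CC/MCC,0.8811
111,SIMPLE PNEUMONIA AND PLEURISY WITH MCC,1.4378
112,SIMPLE PNEUMONIA AND PLEURISY WITH CC,0.9976
113,SIMPLE PNEUMONIA AND PLEURISY WITHOUT CC/MCC,0.7104
121,HEART FAILURE AND SHOCK WITH MCC,1.8119
122,HEART FAILURE AND SHOCK WITH CC,1.2145
123,HEART FAILURE AND SHOCK WITHOUT CC/MCC,0.8936
131,KIDNEY AND URINARY TRACT INFECTIONS WITH MCC,1.5570
132,KIDNEY AND URINARY TRACT INFECTIONS WITH CC,1.0441
133,KIDNEY AND URINARY TRACT INFECTIONS WITHOUT CC/MCC,0.7906
141,ESOPHAGITIS AND MISC DIGESTIVE DISORDERS WITH MCC,1.4997
142,ESOPHAGITIS AND MISC DIGESTIVE DISORDERS WITH CC,0.9545
143,ESOPHAGITIS AND MISC DIGESTIVE DISORDERS WITHOUT CC/MCC,0.6815
151,DISORDERS OF PANCREAS EXCEPT MALIGNANCY WITH MCC,1.7432
152,DISORDERS OF PANCREAS EXCEPT MALIGNANCY WITH CC,1.1206
153,DISORDERS OF PANCREAS EXCEPT MALIGNANCY WITHOUT CC/MCC,0.8213
161,CELLULITIS WITH MCC,1.3916
162,CELLULITIS WITH CC,0.9384
163,CELLULITIS WITHOUT CC/MCC,0.7082
171,SEPTICEMIA OR SEVERE SEPSIS WITH MCC,2.2183
172,SEPTICEMIA OR SEVERE SEPSIS WITH CC,1.5804
173,SEPTICEMIA OR SEVERE SEPSIS WITHOUT CC/MCC,1.0927
181,RENAL FAILURE WITH MCC,1.6705
182,RENAL FAILURE WITH CC,1.1158
183,RENAL FAILURE WITHOUT CC/MCC,0.8254
191,NUTRITIONAL AND MISC METABOLIC DISORDERS WITH MCC,1.4863
192,NUTRITIONAL AND MISC METABOLIC DISORDERS WITH CC,0.9621
193,NUTRITIONAL AND MISC METABOLIC DISORDERS WITHOUT CC/MCC,0.7345
201,CHRONIC OBSTRUCTIVE PULMONARY DISEASE WITH MCC,1.3544
202,CHRONIC OBSTRUCTIVE PULMONARY DISEASE WITH CC,1.0113
203,CHRONIC OBSTRUCTIVE PULMONARY DISEASE WITHOUT CC/MCC,0.8042
211,DIABETES WITH MCC,1.4231
212,DIABETES WITH CC,0.9867
213,DIABETES WITHOUT CC/MCC,0.7518
221,RED BLOOD CELL DISORDERS WITH CC/MCC,1.1921
222,RED BLOOD CELL DISORDERS WITHOUT CC/MCC,0.8308
231,HEART TRANSPLANT,7.9431
232,TRACHEOSTOMY FOR FACE MOUTH AND NECK DIAGNOSES,3.5817
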