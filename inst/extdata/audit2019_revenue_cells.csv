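upgrade_type,payor,count,added_points
base_to_CC,MEDI-CAL,254,75.4941
base_to_CC,MEDICARE,198,72.7078
base_to_CC,PRIVATE,583,183.8997
base_to_MCC,MEDI-CAL,87,133.8745
base_to_MCC,MEDICARE,75,54.3528
base_to_MCC,PRIVATE,32,46.6599
CC_to_MCC,MEDI-CAL,134,201.6356
CC_to_MCC,MEDICARE,296,376.6575
CC_to_MCC,PRIVATE,355,497.484
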