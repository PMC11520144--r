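upgrade_type,count
base_to_CC,1127
base_to_MCC,185
CC_to_MCC,678
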