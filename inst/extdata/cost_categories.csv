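raw_label,group
LAB_CHEM,lab
LAB_HEMA,lab
DIALYZER,medical_supply
PD_SOLUTION,medical_supply
ESA_DRUG,medicine
ANTIHYPERTENSIVE,medicine
VASC_ACCESS_OP,operation
CATHETER_OP,operation
WARD_BED,room
NURSING_SERVICE,service
CHEST_XRAY,xray
MISC_FEE,other
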