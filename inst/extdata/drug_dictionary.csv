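code,name,class
PIPC_TAZ,piperacillin/tazobactam,anti_pseudomonal
MEPM,meropenem,anti_pseudomonal
IPM_CS,imipenem/cilastatin,anti_pseudomonal
DRPM,doripenem,anti_pseudomonal
CFPM,cefepime,anti_pseudomonal
CAZ,ceftazidime,anti_pseudomonal
AZT,aztreonam,anti_pseudomonal
CPFX,ciprofloxacin,anti_pseudomonal
LVFX,levofloxacin,anti_pseudomonal
ABPC_SBT,ampicillin/sulbactam,non_anti_pseudomonal
ABPC,ampicillin,non_anti_pseudomonal
CTRX,ceftriaxone,non_anti_pseudomonal
CEZ,cefazolin,non_anti_pseudomonal
CLDM,clindamycin,non_anti_pseudomonal
VCM,vancomycin,non_anti_pseudomonal
MNZ,metronidazole,non_anti_pseudomonal
NAD,noradrenaline,vasopressor
DOA,dopamine,vasopressor
AVP,vasopressin,vasopressor
ADR,adrenaline,vasopressor
UK,urokinase,other
THORACOSTOMY,thoracostomy,other
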