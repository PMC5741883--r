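index_code,higher_is_better
BBP,TRUE
FBP,TRUE
DEA,FALSE
ANS,TRUE
APH,TRUE
APW,TRUE
NSP,TRUE
NAB,TRUE
NPO,TRUE
NOF,TRUE
ANO,TRUE
ANA,TRUE
POF,TRUE
PAF,FALSE
ADF,TRUE
ADS,TRUE
AOD,TRUE
NDF,TRUE
PFF,TRUE
DFS,FALSE
DFF,FALSE
PPO,TRUE
RCC,TRUE
ALL,TRUE
ALW,TRUE
ALT,TRUE
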