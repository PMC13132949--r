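# Danish oscillometric office BP reference values (mmHg), children aged 4-15.
# Age- and sex-specific 50th/90th/95th percentiles; lookup reference "danish_2025".
outcome,sex,age,p50,p90,p95
sbp,female,4,96,104,107
sbp,female,5,97,105,108
sbp,female,6,99,107,111
sbp,female,7,100,109,112
sbp,female,8,101,110,113
sbp,female,9,103,112,115
sbp,female,10,104,114,116
sbp,female,11,105,115,118
sbp,female,12,107,117,120
sbp,female,13,109,119,121
sbp,female,14,110,120,123
sbp,female,15,111,122,124
dbp,female,4,62,69,70
dbp,female,5,63,69,71
dbp,female,6,63,70,71
dbp,female,7,64,70,72
dbp,female,8,64,71,72
dbp,female,9,65,71,73
dbp,female,10,65,72,73
dbp,female,11,66,73,74
dbp,female,12,66,73,74
dbp,female,13,66,73,75
dbp,female,14,67,74,75
dbp,female,15,67,74,76
sbp,male,4,96,104,109
sbp,male,5,97,106,110
sbp,male,6,99,107,111
sbp,male,7,100,109,113
sbp,male,8,101,111,114
sbp,male,9,103,112,116
sbp,male,10,104,114,118
sbp,male,11,105,116,119
sbp,male,12,107,117,121
sbp,male,13,108,119,122
sbp,male,14,109,120,124
sbp,male,15,111,122,126
dbp,male,4,61,67,69
dbp,male,5,62,68,69
dbp,male,6,62,68,70
dbp,male,7,63,69,70
dbp,male,8,63,69,71
dbp,male,9,64,70,71
dbp,male,10,64,70,72
dbp,male,11,65,71,72
dbp,male,12,65,71,73
dbp,male,13,65,71,73
dbp,male,14,66,72,74
dbp,male,15,66,72,74
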