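term,value
constant_any_dysfunction,0.081
any_level3,0.269
mobility_L2,0.069
mobility_L3,0.314
self_care_L2,0.104
self_care_L3,0.214
usual_activities_L2,0.036
usual_activities_L3,0.094
pain_discomfort_L2,0.123
pain_discomfort_L3,0.386
anxiety_depression_L2,0.071
anxiety_depression_L3,0.236
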