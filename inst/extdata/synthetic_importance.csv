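stakeholder,criterion,score
s001,care_pathway,7
s002,care_pathway,7
s003,care_pathway,8
s004,care_pathway,7
s005,care_pathway,5
s006,care_pathway,7
s007,care_pathway,8
s008,care_pathway,9
s009,care_pathway,7
s010,care_pathway,7
s011,care_pathway,8
s013,care_pathway,5
s014,care_pathway,10
s001,diagnostic_accuracy,9
s003,diagnostic_accuracy,8
s004,diagnostic_accuracy,10
s006,diagnostic_accuracy,7
s007,diagnostic_accuracy,10
s008,diagnostic_accuracy,7
s009,diagnostic_accuracy,10
s010,diagnostic_accuracy,8
s011,diagnostic_accuracy,7
s012,diagnostic_accuracy,9
s013,diagnostic_accuracy,7
s014,diagnostic_accuracy,10
s001,clinical_effectiveness,6
s002,clinical_effectiveness,7
s003,clinical_effectiveness,8
s004,clinical_effectiveness,8
s006,clinical_effectiveness,8
s007,clinical_effectiveness,5
s008,clinical_effectiveness,7
s009,clinical_effectiveness,9
s010,clinical_effectiveness,8
s011,clinical_effectiveness,9
s012,clinical_effectiveness,8
s013,clinical_effectiveness,6
s001,population_size,2
s002,population_size,5
s003,population_size,5
s004,population_size,8
s005,population_size,5
s006,population_size,6
s007,population_size,5
s008,population_size,5
s009,population_size,2
s010,population_size,5
s012,population_size,7
s013,population_size,5
s014,population_size,8
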