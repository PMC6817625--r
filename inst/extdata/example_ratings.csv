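rater_id,rater_country,target_id,display,score
BR_M_speech_rater1,BR,M_BR_001,speech,3
BR_M_speech_rater2,BR,M_BR_001,speech,3
BR_M_speech_rater3,BR,M_BR_001,speech,3
BR_M_speech_rater4,BR,M_BR_001,speech,3
BR_M_speech_rater1,BR,M_BR_002,speech,3
BR_M_speech_rater2,BR,M_BR_002,speech,3
BR_M_speech_rater3,BR,M_BR_002,speech,2
BR_M_speech_rater4,BR,M_BR_002,speech,3
BR_M_speech_rater1,BR,M_BR_003,speech,3
BR_M_speech_rater2,BR,M_BR_003,speech,3
BR_M_speech_rater3,BR,M_BR_003,speech,4
BR_M_speech_rater4,BR,M_BR_003,speech,4
BR_M_speech_rater1,BR,M_BR_004,speech,4
BR_M_speech_rater2,BR,M_BR_004,speech,5
BR_M_speech_rater3,BR,M_BR_004,speech,5
BR_M_speech_rater4,BR,M_BR_004,speech,5
BR_M_speech_rater1,BR,M_CZ_001,speech,3
BR_M_speech_rater2,BR,M_CZ_001,speech,3
BR_M_speech_rater3,BR,M_CZ_001,speech,4
BR_M_speech_rater4,BR,M_CZ_001,speech,3
BR_M_speech_rater1,BR,M_CZ_002,speech,4
BR_M_speech_rater2,BR,M_CZ_002,speech,4
BR_M_speech_rater3,BR,M_CZ_002,speech,3
BR_M_speech_rater4,BR,M_CZ_002,speech,3
CZ_M_speech_rater1,CZ,M_BR_001,speech,3
CZ_M_speech_rater2,CZ,M_BR_001,speech,2
CZ_M_speech_rater3,CZ,M_BR_001,speech,2
CZ_M_speech_rater4,CZ,M_BR_001,speech,4
CZ_M_speech_rater1,CZ,M_BR_002,speech,3
CZ_M_speech_rater2,CZ,M_BR_002,speech,3
CZ_M_speech_rater3,CZ,M_BR_002,speech,3
CZ_M_speech_rater4,CZ,M_BR_002,speech,3
CZ_M_speech_rater1,CZ,M_BR_003,speech,3
CZ_M_speech_rater2,CZ,M_BR_003,speech,4
CZ_M_speech_rater3,CZ,M_BR_003,speech,3
CZ_M_speech_rater4,CZ,M_BR_003,speech,4
CZ_M_speech_rater1,CZ,M_BR_004,speech,4
CZ_M_speech_rater2,CZ,M_BR_004,speech,4
CZ_M_speech_rater3,CZ,M_BR_004,speech,5
CZ_M_speech_rater4,CZ,M_BR_004,speech,4
CZ_M_speech_rater1,CZ,M_CZ_001,speech,3
CZ_M_speech_rater2,CZ,M_CZ_001,speech,4
CZ_M_speech_rater3,CZ,M_CZ_001,speech,2
CZ_M_speech_rater4,CZ,M_CZ_001,speech,4
CZ_M_speech_rater1,CZ,M_CZ_002,speech,4
CZ_M_speech_rater2,CZ,M_CZ_002,speech,3
CZ_M_speech_rater3,CZ,M_CZ_002,speech,4
CZ_M_speech_rater4,CZ,M_CZ_002,speech,5
BR_M_singing_rater1,BR,M_BR_001,singing,2
BR_M_singing_rater2,BR,M_BR_001,singing,2
BR_M_singing_rater3,BR,M_BR_001,singing,3
BR_M_singing_rater4,BR,M_BR_001,singing,2
BR_M_singing_rater1,BR,M_BR_002,singing,3
BR_M_singing_rater2,BR,M_BR_002,singing,2
BR_M_singing_rater3,BR,M_BR_002,singing,4
BR_M_singing_rater4,BR,M_BR_002,singing,3
BR_M_singing_rater1,BR,M_BR_003,singing,3
BR_M_singing_rater2,BR,M_BR_003,singing,3
BR_M_singing_rater3,BR,M_BR_003,singing,3
BR_M_singing_rater4,BR,M_BR_003,singing,4
BR_M_singing_rater1,BR,M_BR_004,singing,4
BR_M_singing_rater2,BR,M_BR_004,singing,4
BR_M_singing_rater3,BR,M_BR_004,singing,4
BR_M_singing_rater4,BR,M_BR_004,singing,3
BR_M_singing_rater1,BR,M_CZ_001,singing,3
BR_M_singing_rater2,BR,M_CZ_001,singing,2
BR_M_singing_rater3,BR,M_CZ_001,singing,4
BR_M_singing_rater4,BR,M_CZ_001,singing,3
BR_M_singing_rater1,BR,M_CZ_002,singing,2
BR_M_singing_rater2,BR,M_CZ_002,singing,3
BR_M_singing_rater3,BR,M_CZ_002,singing,2
BR_M_singing_rater4,BR,M_CZ_002,singing,2
CZ_M_singing_rater1,CZ,M_BR_001,singing,3
CZ_M_singing_rater2,CZ,M_BR_001,singing,2
CZ_M_singing_rater3,CZ,M_BR_001,singing,3
CZ_M_singing_rater4,CZ,M_BR_001,singing,2
CZ_M_singing_rater1,CZ,M_BR_002,singing,4
CZ_M_singing_rater2,CZ,M_BR_002,singing,2
CZ_M_singing_rater3,CZ,M_BR_002,singing,3
CZ_M_singing_rater4,CZ,M_BR_002,singing,3
CZ_M_singing_rater1,CZ,M_BR_003,singing,4
CZ_M_singing_rater2,CZ,M_BR_003,singing,2
CZ_M_singing_rater3,CZ,M_BR_003,singing,4
CZ_M_singing_rater4,CZ,M_BR_003,singing,3
CZ_M_singing_rater1,CZ,M_BR_004,singing,4
CZ_M_singing_rater2,CZ,M_BR_004,singing,3
CZ_M_singing_rater3,CZ,M_BR_004,singing,4
CZ_M_singing_rater4,CZ,M_BR_004,singing,5
CZ_M_singing_rater1,CZ,M_CZ_001,singing,4
CZ_M_singing_rater2,CZ,M_CZ_001,singing,2
CZ_M_singing_rater3,CZ,M_CZ_001,singing,4
CZ_M_singing_rater4,CZ,M_CZ_001,singing,4
CZ_M_singing_rater1,CZ,M_CZ_002,singing,3
CZ_M_singing_rater2,CZ,M_CZ_002,singing,2
CZ_M_singing_rater3,CZ,M_CZ_002,singing,3
CZ_M_singing_rater4,CZ,M_CZ_002,singing,3
BR_F_speech_rater1,BR,F_BR_001,speech,4
BR_F_speech_rater2,BR,F_BR_001,speech,4
BR_F_speech_rater3,BR,F_BR_001,speech,4
BR_F_speech_rater4,BR,F_BR_001,speech,4
BR_F_speech_rater1,BR,F_BR_002,speech,4
BR_F_speech_rater2,BR,F_BR_002,speech,3
BR_F_speech_rater3,BR,F_BR_002,speech,4
BR_F_speech_rater4,BR,F_BR_002,speech,4
BR_F_speech_rater1,BR,F_BR_003,speech,4
BR_F_speech_rater2,BR,F_BR_003,speech,3
BR_F_speech_rater3,BR,F_BR_003,speech,4
BR_F_speech_rater4,BR,F_BR_003,speech,3
BR_F_speech_rater1,BR,F_BR_004,speech,4
BR_F_speech_rater2,BR,F_BR_004,speech,4
BR_F_speech_rater3,BR,F_BR_004,speech,4
BR_F_speech_rater4,BR,F_BR_004,speech,3
BR_F_speech_rater1,BR,F_CZ_001,speech,5
BR_F_speech_rater2,BR,F_CZ_001,speech,5
BR_F_speech_rater3,BR,F_CZ_001,speech,5
BR_F_speech_rater4,BR,F_CZ_001,speech,4
BR_F_speech_rater1,BR,F_CZ_002,speech,4
BR_F_speech_rater2,BR,F_CZ_002,speech,4
BR_F_speech_rater3,BR,F_CZ_002,speech,4
BR_F_speech_rater4,BR,F_CZ_002,speech,3
CZ_F_speech_rater1,CZ,F_BR_001,speech,4
CZ_F_speech_rater2,CZ,F_BR_001,speech,4
CZ_F_speech_rater3,CZ,F_BR_001,speech,3
CZ_F_speech_rater4,CZ,F_BR_001,speech,4
CZ_F_speech_rater1,CZ,F_BR_002,speech,4
CZ_F_speech_rater2,CZ,F_BR_002,speech,4
CZ_F_speech_rater3,CZ,F_BR_002,speech,4
CZ_F_speech_rater4,CZ,F_BR_002,speech,4
CZ_F_speech_rater1,CZ,F_BR_003,speech,3
CZ_F_speech_rater2,CZ,F_BR_003,speech,4
CZ_F_speech_rater3,CZ,F_BR_003,speech,3
CZ_F_speech_rater4,CZ,F_BR_003,speech,4
CZ_F_speech_rater1,CZ,F_BR_004,speech,3
CZ_F_speech_rater2,CZ,F_BR_004,speech,3
CZ_F_speech_rater3,CZ,F_BR_004,speech,3
CZ_F_speech_rater4,CZ,F_BR_004,speech,4
CZ_F_speech_rater1,CZ,F_CZ_001,speech,4
CZ_F_speech_rater2,CZ,F_CZ_001,speech,5
CZ_F_speech_rater3,CZ,F_CZ_001,speech,4
CZ_F_speech_rater4,CZ,F_CZ_001,speech,5
CZ_F_speech_rater1,CZ,F_CZ_002,speech,4
CZ_F_speech_rater2,CZ,F_CZ_002,speech,4
CZ_F_speech_rater3,CZ,F_CZ_002,speech,4
CZ_F_speech_rater4,CZ,F_CZ_002,speech,4
BR_F_singing_rater1,BR,F_BR_001,singing,4
BR_F_singing_rater2,BR,F_BR_001,singing,4
BR_F_singing_rater3,BR,F_BR_001,singing,5
BR_F_singing_rater4,BR,F_BR_001,singing,4
BR_F_singing_rater1,BR,F_BR_002,singing,3
BR_F_singing_rater2,BR,F_BR_002,singing,4
BR_F_singing_rater3,BR,F_BR_002,singing,4
BR_F_singing_rater4,BR,F_BR_002,singing,3
BR_F_singing_rater1,BR,F_BR_003,singing,3
BR_F_singing_rater2,BR,F_BR_003,singing,4
BR_F_singing_rater3,BR,F_BR_003,singing,3
BR_F_singing_rater4,BR,F_BR_003,singing,4
BR_F_singing_rater1,BR,F_BR_004,singing,4
BR_F_singing_rater2,BR,F_BR_004,singing,4
BR_F_singing_rater3,BR,F_BR_004,singing,3
BR_F_singing_rater4,BR,F_BR_004,singing,4
BR_F_singing_rater1,BR,F_CZ_001,singing,4
BR_F_singing_rater2,BR,F_CZ_001,singing,4
BR_F_singing_rater3,BR,F_CZ_001,singing,4
BR_F_singing_rater4,BR,F_CZ_001,singing,4
BR_F_singing_rater1,BR,F_CZ_002,singing,4
BR_F_singing_rater2,BR,F_CZ_002,singing,4
BR_F_singing_rater3,BR,F_CZ_002,singing,4
BR_F_singing_rater4,BR,F_CZ_002,singing,4
CZ_F_singing_rater1,CZ,F_BR_001,singing,4
CZ_F_singing_rater2,CZ,F_BR_001,singing,4
CZ_F_singing_rater3,CZ,F_BR_001,singing,4
CZ_F_singing_rater4,CZ,F_BR_001,singing,4
CZ_F_singing_rater1,CZ,F_BR_002,singing,3
CZ_F_singing_rater2,CZ,F_BR_002,singing,4
CZ_F_singing_rater3,CZ,F_BR_002,singing,3
CZ_F_singing_rater4,CZ,F_BR_002,singing,4
CZ_F_singing_rater1,CZ,F_BR_003,singing,3
CZ_F_singing_rater2,CZ,F_BR_003,singing,3
CZ_F_singing_rater3,CZ,F_BR_003,singing,4
CZ_F_singing_rater4,CZ,F_BR_003,singing,4
CZ_F_singing_rater1,CZ,F_BR_004,singing,3
CZ_F_singing_rater2,CZ,F_BR_004,singing,4
CZ_F_singing_rater3,CZ,F_BR_004,singing,4
CZ_F_singing_rater4,CZ,F_BR_004,singing,4
CZ_F_singing_rater1,CZ,F_CZ_001,singing,3
CZ_F_singing_rater2,CZ,F_CZ_001,singing,4
CZ_F_singing_rater3,CZ,F_CZ_001,singing,4
CZ_F_singing_rater4,CZ,F_CZ_001,singing,4
CZ_F_singing_rater1,CZ,F_CZ_002,singing,4
CZ_F_singing_rater2,CZ,F_CZ_002,singing,4
CZ_F_singing_rater3,CZ,F_CZ_002,singing,3
CZ_F_singing_rater4,CZ,F_CZ_002,singing,5
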