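person_id,sex,country,age,height_cm,weight_kg,wsr,whr,speech_f0_st,singing_f0_st,speech_range_st,singing_range_st,speech_vtl_cm,singing_vtl_cm,attract_speech,attract_singing,soi_total,liking_to_sing
M_BR_001,M,BR,21.6302465916,179.52953082,77.8646157413,0.72398500822,NA,-28.1535348871,-27.1744314315,16.4632283755,17.2795545785,18.2817642921,17.8607049371,3.1873562293,2.7446316034,40.7799365171,2
M_BR_002,M,BR,14.7286892474,181.999717182,88.0334915864,0.72286024918,NA,-21.7525015798,-21.924347235,10.0031417013,16.948359371,17.6666273705,17.3092984574,3.1929690576,3.12476703858,27.0506836949,6
M_BR_003,M,BR,18.5888243261,174.396325979,61.477343584,0.712658442835,NA,-19.1624999841,-17.9490188812,13.1549548029,14.6849805355,17.672985964,16.9775020205,3.56875477936,3.63227003606,39.2989390707,6
M_BR_004,M,BR,17.7513780099,181.094198929,74.5242532072,0.689217447206,NA,-24.2628420323,-21.7775142939,15.0922699907,14.1558102568,18.0598086828,17.5086240962,4.72352991784,3.95100186725,45.0103249859,10
M_CZ_001,M,CZ,21.3293277603,185.880241848,95.3602102133,0.732891250624,NA,-21.6509152197,-18.5563231055,10.2417200206,15.4914542987,17.8388023823,17.2813144224,3.62568270458,3.20557767637,49.2524739287,7
M_CZ_002,M,CZ,23.1828482866,183.226819656,75.9452603115,0.820586733225,NA,-22.127907902,-21.299324904,12.5146719198,13.808973996,17.6885286048,17.0646021782,3.68008078016,2.72867838487,44.097953543,9
F_BR_001,F,BR,28.5704485861,172.64311368,73.1153647918,NA,0.632827273056,-14.2864653098,-13.2096660078,7.731065359,12.4558587769,14.3645894089,14.2161548833,4.04734168718,4.33335573022,56.0838385212,10
F_BR_002,F,BR,30.5338766346,153.712782209,63.2162833098,NA,0.724125776297,-13.4261756464,-10.7728035465,9.72881957532,13.3535448719,14.0286471008,13.9524090891,3.75041901804,3.21886635059,9,8
F_BR_003,F,BR,21.0356488567,167.194672246,52.848124704,NA,0.698294545384,-11.4163347908,-7.40570903914,19.276784989,14.3473009435,13.8163087492,14.0588338624,3.52557971762,3.36332235258,36.567260635,10
F_BR_004,F,BR,23.1427935484,153.349139837,52.2694280786,NA,0.74452459211,-13.8340005163,-8.76060338367,8.31214416339,12.5807507967,14.1510284313,14.196720436,3.46006808826,3.49145134262,52.3957330443,10
F_CZ_001,F,CZ,23.9809241095,171.135064699,70.0946484498,NA,0.722816232798,-9.97316363565,-7.17722448001,19.2496244674,17.8182027495,13.496758957,13.5338038314,4.44452198803,3.81655628704,15.7319305682,8
F_CZ_002,F,CZ,20.9188012796,184.403553833,81.7689433406,NA,0.648312389589,-15.4362164284,-11.9909679923,16.9582748339,16.5587784443,15.130101105,14.8153967906,3.77271630569,3.70055478571,39.0250696023,8
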