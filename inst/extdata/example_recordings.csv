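recording_id,person_id,display,item,mean_f0_hz,min_f0_hz,max_f0_hz,f1_hz,f2_hz,f3_hz,f4_hz
M_BR_001_speech_self-presentation,M_BR_001,speech,self-presentation,85.7251698491,44.5184305738,118.957713675,461.645285785,1386.26821463,2330.32894851,3244.55828229
M_BR_001_speech_anthem-spoken,M_BR_001,speech,anthem-spoken,86.2549019137,44.1690754327,120.535930322,461.363600097,1365.89868393,2327.50063953,3165.50883457
M_BR_001_singing_birthday-song,M_BR_001,singing,birthday-song,90.947492278,47.1023683689,126.376033617,472.552994815,1405.24562333,2312.96873046,3300.52446952
M_BR_001_singing_anthem-sung,M_BR_001,singing,anthem-sung,93.4644300704,48.5452444388,129.686926239,478.277348112,1404.14237522,2384.80280696,3319.23707959
M_BR_002_speech_self-presentation,M_BR_002,speech,self-presentation,126.950259925,84.7249659077,155.39773707,471.79603843,1425.67353121,2303.64534869,3332.56511485
M_BR_002_speech_anthem-spoken,M_BR_002,speech,anthem-spoken,122.655574168,82.9061065012,149.189299483,462.519078498,1417.4745737,2363.25703095,3317.63955574
M_BR_002_singing_birthday-song,M_BR_002,singing,birthday-song,115.976776658,61.4629309137,159.312524019,490.492005877,1473.90896257,2425.37111316,3409.74511471
M_BR_002_singing_anthem-sung,M_BR_002,singing,anthem-sung,118.809181787,64.6612761191,161.047086282,487.800375047,1434.66787605,2443.15240473,3359.29537512
M_BR_003_speech_self-presentation,M_BR_003,speech,self-presentation,146.1570474,84.3185170497,192.427953731,467.205207093,1403.98131418,2312.95695815,3263.4242509
M_BR_003_speech_anthem-spoken,M_BR_003,speech,anthem-spoken,145.933818953,86.5139937094,189.535576792,469.08756468,1419.11881869,2360.31992533,3303.88007491
M_BR_003_singing_birthday-song,M_BR_003,singing,birthday-song,162.97654406,86.984821957,223.082712749,487.94568868,1438.32702209,2416.29274288,3428.61253246
M_BR_003_singing_anthem-sung,M_BR_003,singing,anthem-sung,150.368689504,84.9677012176,200.036472662,502.662966773,1497.02571452,2454.99228203,3435.86623207
M_BR_004_speech_self-presentation,M_BR_004,speech,self-presentation,103.065492601,56.6029515093,139.075421911,469.967274734,1401.22176601,2354.57794984,3289.0381047
M_BR_004_speech_anthem-spoken,M_BR_004,speech,anthem-spoken,108.235390819,61.3769629267,143.73126143,467.843129783,1388.51830037,2322.25925415,3310.26864393
M_BR_004_singing_birthday-song,M_BR_004,singing,birthday-song,126.877647793,75.9040239608,164.038306787,474.413432103,1462.26458627,2414.18253614,3365.62467483
M_BR_004_singing_anthem-sung,M_BR_004,singing,anthem-sung,124.237967854,71.7870753794,163.440009321,485.180662841,1487.02075039,2423.43461302,3410.59202303
M_CZ_001_speech_self-presentation,M_CZ_001,speech,self-presentation,125.415853837,79.4831974985,157.540055403,462.867859754,1390.5759993,2312.97135463,3245.96937471
M_CZ_001_speech_anthem-spoken,M_CZ_001,speech,anthem-spoken,129.606596448,89.6211130893,155.860294358,463.013076411,1410.08980697,2373.02857945,3282.35067285
M_CZ_001_singing_birthday-song,M_CZ_001,singing,birthday-song,147.399237774,82.1153423484,197.483448634,471.783134231,1421.95917731,2394.48632531,3339.28177126
M_CZ_001_singing_anthem-sung,M_CZ_001,singing,anthem-sung,143.805310773,76.3455012444,197.365237731,501.185303614,1505.08434268,2498.71398096,3433.69865191
M_CZ_002_speech_self-presentation,M_CZ_002,speech,self-presentation,119.384916503,74.698129791,150.927829241,480.25068167,1447.2584936,2389.14376289,3370.199974
M_CZ_002_speech_anthem-spoken,M_CZ_002,speech,anthem-spoken,120.909272532,75.3645456244,153.146074653,472.332996006,1429.42920374,2358.46784616,3351.28119033
M_CZ_002_singing_birthday-song,M_CZ_002,singing,birthday-song,127.084258127,83.2460344112,157.020320659,499.218148192,1462.41214281,2450.03803956,3422.85401089
M_CZ_002_singing_anthem-sung,M_CZ_002,singing,anthem-sung,130.0421507,80.9652298957,164.807487467,493.11027569,1504.76429091,2469.19556087,3439.52719053
F_BR_001_speech_self-presentation,F_BR_001,speech,self-presentation,192.773299622,153.712418901,215.881706867,577.782605446,1753.30793166,2929.34921497,4077.56303571
F_BR_001_speech_anthem-spoken,F_BR_001,speech,anthem-spoken,199.683867404,148.366586459,231.657527419,590.517906397,1733.06543711,2943.01499195,4044.49387078
F_BR_001_singing_birthday-song,F_BR_001,singing,birthday-song,205.818104233,124.716713232,264.400962618,580.712862096,1754.21104939,2922.89827483,4092.45533225
F_BR_001_singing_anthem-sung,F_BR_001,singing,anthem-sung,215.599312072,132.421404591,275.100868274,594.459304981,1764.24314366,2904.08476956,4101.04564401
F_BR_002_speech_self-presentation,F_BR_002,speech,self-presentation,198.40774424,126.450164333,248.529662592,600.278960952,1798.35467825,2960.65390765,4220.85569899
F_BR_002_speech_anthem-spoken,F_BR_002,speech,anthem-spoken,198.029932923,129.95485131,244.455612194,590.738418988,1779.28151541,2962.51768687,4132.85978369
F_BR_002_singing_birthday-song,F_BR_002,singing,birthday-song,246.877214115,160.475847086,306.208099142,596.674651713,1812.42387339,3003.15018257,4189.34889396
F_BR_002_singing_anthem-sung,F_BR_002,singing,anthem-sung,235.616548077,138.444733856,307.3763599,599.61976301,1781.1738241,2957.08249143,4177.87523164
F_BR_003_speech_self-presentation,F_BR_003,speech,self-presentation,224.190395414,108.401182858,322.409992762,598.746425019,1805.32406767,2975.75093587,4219.94234939
F_BR_003_speech_anthem-spoken,F_BR_003,speech,anthem-spoken,232.875311194,113.866206992,333.033364851,602.020476784,1787.15905343,3004.11138871,4167.20094274
F_BR_003_singing_birthday-song,F_BR_003,singing,birthday-song,295.752210979,171.5663127,388.307689909,588.633705586,1738.34485122,2966.81038569,4140.86654695
F_BR_003_singing_anthem-sung,F_BR_003,singing,anthem-sung,281.448789868,171.318522003,360.742174678,598.823197243,1772.22774493,2970.6827419,4154.1992885
F_BR_004_speech_self-presentation,F_BR_004,speech,self-presentation,202.626113569,149.093413832,236.218491849,593.163492027,1796.68384828,3021.55371345,4151.94878829
F_BR_004_speech_anthem-spoken,F_BR_004,speech,anthem-spoken,197.046844011,144.632240286,229.996733725,609.934391784,1791.36527811,3068.55658397,4237.41534156
F_BR_004_singing_birthday-song,F_BR_004,singing,birthday-song,266.824890393,164.511411056,339.814178733,581.51016232,1777.60244011,2939.51695147,4079.01974104
F_BR_004_singing_anthem-sung,F_BR_004,singing,anthem-sung,268.350761266,172.792271535,334.419882928,590.033754302,1747.73373094,2941.56078319,4056.65991092
F_CZ_001_speech_self-presentation,F_CZ_001,speech,self-presentation,239.080811007,123.749705915,332.311210781,623.765954822,1874.84962455,3045.38381477,4315.05977715
F_CZ_001_speech_anthem-spoken,F_CZ_001,speech,anthem-spoken,253.443185107,126.898801263,358.172441247,620.422149145,1894.42978876,3105.46204659,4375.63975437
F_CZ_001_singing_birthday-song,F_CZ_001,singing,birthday-song,295.114337923,145.11524912,420.851557722,625.741286298,1857.53596087,3098.28498228,4297.09478315
F_CZ_001_singing_anthem-sung,F_CZ_001,singing,anthem-sung,288.667736793,138.867662327,416.194952172,617.13150859,1834.21636629,3104.73075997,4267.35733355
F_CZ_002_speech_self-presentation,F_CZ_002,speech,self-presentation,186.011107297,98.443861341,255.690149483,549.448916043,1628.44107933,2775.57639912,3926.024244
F_CZ_002_speech_anthem-spoken,F_CZ_002,speech,anthem-spoken,167.991893672,87.9364415851,232.192423615,540.309046082,1642.53397698,2721.54177633,3775.94666397
F_CZ_002_singing_birthday-song,F_CZ_002,singing,birthday-song,213.542158721,112.664486962,293.989568905,567.375744578,1714.98210299,2856.1305603,3933.75943217
F_CZ_002_singing_anthem-sung,F_CZ_002,singing,anthem-sung,223.207323161,118.996584069,305.699980787,575.343938447,1695.43429638,2800.98230489,4040.82848676
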