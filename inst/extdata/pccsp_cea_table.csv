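entry_age,age_group,strategy,qalys,inc_qaly_vs_none,inc_qaly_vs_next,cost_thousand,inc_cost_vs_none,inc_cost_vs_next,icer_vs_none,icer_vs_next
42,40-44,none,2064861,,,105827,,,,
42,40-44,once,2066380,1519,1519,118197,12370,12370,8144,8144
42,40-44,every_10y,2068402,3541,2022,157206,51379,39009,14509,19289
42,40-44,every_5y,2070731,5870,2329,195957,90129,38751,15354,16640
42,40-44,every_3y,2073634,8773,2903,247221,141394,51264,16118,17661
42,40-44,every_2y,2077090,12229,3457,324338,218510,77117,17868,22310
42,40-44,annual,2084817,19955,7726,528415,422588,204077,21177,26414
47,45-49,none,1898860,,,102463,,,,
47,45-49,once,1900407,1546,1546,114991,12529,12529,8102,8102
47,45-49,every_10y,1901953,3093,1547,140916,38453,25925,12433,16762
47,45-49,every_5y,1904293,5432,2339,179431,76968,38515,14169,16465
47,45-49,every_3y,1907096,8236,2804,230810,128348,51380,15584,18327
47,45-49,every_2y,1909915,11055,2819,281726,179264,50916,16216,18062
47,45-49,annual,1917203,18342,7287,459372,356910,177646,19459,24377
52,50-54,none,1708991,,,98999,,,,
52,50-54,once,1710812,1821,1821,111232,12233,12233,6718,6718
52,50-54,every_10y,1712179,3188,1367,137158,38160,25927,11970,18966
52,50-54,every_5y,1713993,5002,1815,162712,63713,25553,12736,14083
52,50-54,every_3y,1716414,7423,2420,200786,101787,38074,13713,15730
52,50-54,every_2y,1719086,10096,2673,251841,152842,51055,15140,19103
52,50-54,annual,1725353,16362,6267,390775,291776,138934,17832,22171
57,55-59,none,1499103,,,91176,,,,
57,55-59,once,1500874,1771,1771,103523,12347,12347,6971,6971
57,55-59,every_10y,1501662,2559,788,116451,25276,12929,9877,16409
57,55-59,every_5y,1503318,4216,1657,141995,50819,25544,12055,15418
57,55-59,every_3y,1505139,6036,1820,167151,75976,25156,12587,13820
57,55-59,every_2y,1507270,8168,2132,205461,114285,38310,13993,17972
57,55-59,annual,1512601,13498,5331,318771,227595,113310,16861,21255
62,60-64,none,1266933,,,79556,,,,
62,60-64,once,1268627,1695,1695,91684,12127,12127,7156,7156
62,60-64,every_10y,1269229,2296,601,104764,25208,13080,10980,21758
62,60-64,every_5y,1270199,3267,971,117450,37894,12686,11600,13067
62,60-64,every_3y,1271715,4782,1515,143100,63544,25650,13289,16928
62,60-64,every_2y,1273272,6339,1557,168229,88673,25129,13989,16140
62,60-64,annual,1277088,10156,3817,243514,163957,75285,16145,19725
67,65-69,none,1010441,,,67551,,,,
67,65-69,once,1011915,1474,1474,80082,12531,12531,8501,8501
67,65-69,every_5y,1012697,2256,782,92989,25438,12907,11277,16512
67,65-69,every_3y,1013614,3173,917,105454,37904,12465,11947,13593
67,65-69,every_2y,1014320,3879,706,118598,51047,13143,13160,18615
67,65-69,annual,1016997,6555,2677,169045,101495,50448,15483,18848
72,70-74,none,727150,,,50040,,,,
72,70-74,once,728356,1206,1206,62789,12749,12749,10574,10574
72,70-74,every_2y,728990,1839,634,76242,26202,13453,14244,21229
72,70-74,annual,729747,2597,758,89150,39110,12908,15059,17035
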