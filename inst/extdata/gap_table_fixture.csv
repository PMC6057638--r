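feature,sp,ln,status,total,range_pct,target_pct,cells0,pct0,cells1,pct1,cells2,pct2,cells3,pct3,pa_cells,achievement
CHmo,1,1,NT,292535,85.3,10.3,2947,1.0,73689,25.2,210830,72.1,5069,1.7,289588,961.9
DIvi,1,0,LC,136499,39.8,15.9,1434,1.1,22567,16.5,109478,80.2,3020,2.2,135065,623.4
DIvi_1,0,1,,89221,26.0,19.5,1372,1.5,13703,15.4,71175,79.8,2971,3.3,87849,504.6
DIvi_2,0,1,,104923,30.6,18.1,1434,1.4,17771,16.9,83747,79.8,1971,1.9,103489,545.8
HAri,1,0,LC,276256,80.6,10.7,2834,1.0,60715,22.0,207751,75.2,4956,1.8,273422,927.0
HAri_1,0,1,,201130,58.7,12.9,2834,1.4,54848,27.3,139228,69.2,4220,2.1,198296,764.1
HAri_2,0,1,,209015,61.0,12.6,2445,1.2,50538,24.2,152498,73.0,3534,1.7,206570,782.8
HAtr,1,0,LC,235772,68.8,11.8,3134,1.3,76541,32.5,152539,64.7,3558,1.5,232638,838.5
HAtr_1,0,1,,224772,65.6,12.1,3134,1.4,76541,34.1,141539,63.0,3558,1.6,221638,814.6
HAtr_2,0,1,,70733,20.6,21.7,0,0.0,14725,20.8,53721,75.9,2287,3.2,70733,460.7
HEdr,1,1,CR,2275,0.7,100.0,0,0.0,0,0.0,1833,80.6,442,19.4,2275,100.0
HEgr,1,1,NT,4623,1.3,90.4,0,0.0,0,0.0,2908,62.9,1715,37.1,4623,110.6
HEHo,1,0,NE,276100,80.5,10.7,2915,1.1,66317,24.0,201666,73.0,5202,1.9,273185,926.4
HEHo_1,0,1,,64989,19.0,22.5,2529,3.9,21287,32.8,38387,59.1,2786,4.3,62460,426.3
HEHo_2,0,1,,128216,37.4,16.4,2262,1.8,19242,15.0,103189,80.5,3523,2.7,125954,599.7
HEHo_3,0,1,,191269,55.8,13.3,538,0.3,46114,24.1,141186,73.8,3431,1.8,190731,751.3
HEin,1,0,LC,187232,54.6,13.4,1756,0.9,33352,17.8,148103,79.1,4021,2.1,185476,737.6
HEin_1,0,1,,60720,17.7,23.2,1630,2.7,18974,31.2,38799,63.9,1317,2.2,59090,418.7
HEin_2,0,1,,146717,42.8,15.3,1630,1.1,28482,19.4,113327,77.2,3278,2.2,145087,646.5
HEin_3,0,1,,45783,13.4,26.3,0,0.0,11396,24.9,33195,72.5,1192,2.6,45783,380.1
HEin_4,0,1,,84544,24.7,20.0,304,0.4,20665,24.4,62774,74.3,801,0.9,84240,498.1
HEin_5,0,1,,41857,12.2,27.4,1630,3.9,12144,29.0,26813,64.1,1270,3.0,40227,351.3
HEpu,1,0,LC,184829,53.9,13.5,2849,1.5,57635,31.2,121274,65.6,3071,1.7,181980,727.9
HEpu_1,0,1,,151231,44.1,15.1,2849,1.9,46171,30.5,99848,66.0,2363,1.6,148382,651.6
HEpu_2,0,1,,74310,21.7,21.2,2816,3.8,22010,29.6,47913,64.5,1571,2.1,71494,453.3
HEpu_3,0,1,,36042,10.5,29.2,2474,6.9,9602,26.6,22992,63.8,974,2.7,33568,319.1
HEpu_4,0,1,,28345,8.3,32.4,612,2.2,10755,37.9,16334,57.6,644,2.3,27733,302.2
HEpu_5,0,1,,22302,6.5,36.0,375,1.7,4835,21.7,16348,73.3,744,3.3,21927,273.4
HEpu_6,0,1,,31227,9.1,31.0,0,0.0,5315,17.0,25910,83.0,2,0.0,31227,322.1
HKsi,1,0,NT,57770,16.8,23.8,1228,2.1,6738,11.7,48045,83.2,1759,3.0,56542,411.9
HKsi_1,0,1,,57526,16.8,23.8,1226,2.1,6721,11.7,47820,83.1,1759,3.1,56300,411.1
HKsi_2,0,1,,24716,7.2,34.4,864,3.5,5683,23.0,18071,73.1,98,0.4,23852,280.8
HMso,1,1,NT,99927,29.1,18.5,2597,2.6,62166,62.2,33695,33.7,1469,1.5,97330,526.6
MEba,1,0,LC,305669,89.2,10.0,3150,1.0,82315,26.9,214514,70.2,5690,1.9,302519,989.7
MEba_1,0,1,,302942,88.4,10.1,3150,1.0,82124,27.1,211978,70.0,5690,1.9,299792,983.8
MEba_2,0,1,,90147,26.3,19.4,455,0.5,14125,15.7,74563,82.7,1004,1.1,89692,512.4
MYfi,1,1,DD,1,0.0,100.0,0,0.0,1,100.0,0,0.0,0,0.0,1,100.0
MYma,1,0,DD,150436,43.9,15.1,2024,1.3,49215,32.7,98343,65.4,854,0.6,148412,218.7
MYma_1,0,1,,147860,43.1,15.2,2024,1.4,49214,33.3,95822,64.8,800,0.5,145836,647.4
MYma_2,0,1,,136390,39.8,15.9,1634,1.2,39785,29.2,94117,69.0,854,0.6,134756,622.2
MYwi,1,1,DD,5,0.0,100.0,0,0.0,0,0.0,5,100.0,0,0.0,5,100.0
PAbr,1,1,DD,9626,2.8,83.6,924,9.6,5847,60.7,2833,29.4,22,0.2,8702,108.1
PRgu,1,1,LC,86085,25.1,19.8,955,1.1,9394,10.9,73432,85.3,2304,2.7,85130,498.5
PRid,1,1,LC,4329,1.3,97.8,0,0.0,0,0.0,2647,61.1,1682,38.9,4329,102.3
PRin,1,0,LC,250861,73.2,11.3,1992,0.8,50522,20.1,193202,77.0,5145,2.1,248869,875.2
PRin_1,0,1,,220379,64.3,12.2,1992,0.9,50245,22.8,163958,74.4,4184,1.9,218387,809.3
PRin_2,0,1,,75194,21.9,21.1,224,0.3,15328,20.4,57633,76.6,2009,2.7,74970,472.3
PRin_3,0,1,,132040,38.5,16.1,219,0.2,31207,23.6,98746,74.8,1868,1.4,131821,618.5
PRob,1,1,LC,140257,40.9,15.7,2704,1.9,60278,43.0,75177,53.6,2098,1.5,137553,626.5
PRso,1,0,LC,268762,78.4,10.9,2800,1.0,65578,24.4,194858,72.5,5526,2.1,265962,911.0
PRso_1,0,1,,86988,25.4,19.7,2470,2.8,21573,24.8,59679,68.6,3266,3.8,84518,492.1
PRso_2,0,1,,160917,46.9,14.6,2266,1.4,35332,22.0,119640,74.3,3679,2.3,158651,676.4
PRso_3,0,1,,159275,46.5,14.7,330,0.2,47553,29.9,109545,68.8,1847,1.2,158945,681.0
TRso,1,0,LC,248971,72.6,11.4,2865,1.2,67633,27.2,173417,69.7,5056,2.0,246106,868.0
TRso_1,0,1,,236304,68.9,11.8,1733,0.7,67301,28.5,163445,69.2,3825,1.6,234571,844.7
TRso_2,0,1,,180283,52.6,13.7,2621,1.5,36674,20.3,136050,75.5,4938,2.7,177662,718.7
XEso,1,1,DD,5,0.0,100.0,0,0.0,1,20.0,4,80.0,0,0.0,5,100.0
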