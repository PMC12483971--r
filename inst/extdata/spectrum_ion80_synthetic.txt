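# synthetic ion-like spectrum, nominal LET 80 keV/um
# y_keV_um  f_y
17.850412811874378 1.3613666838344244e-09
18.306143588157401 2.4187156008419747e-09
18.773509419754848 4.2538116018637156e-09
19.252807355975701 7.405518220627195e-09
19.744342029959803 1.276193170122658e-08
20.248425852297256 2.1770135648556189e-08
20.76537920959094 3.6761194272539398e-08
21.295530668088468 6.1447164458017602e-08
21.839217182513 1.0167117420444373e-07
22.396784310225556 1.6652428961218563e-07
22.968586430855094 2.6998590876820799e-07
23.554986971535818 4.3329967558986573e-07
24.156358637894908 6.883659625457332e-07
24.773083650937512 1.0825156144365971e-06
25.40555398997952 1.685127278573998e-06
26.054171641782599 2.5966595117590642e-06
26.719348856049717 3.9607831108962813e-06
27.401508407443643 5.9804088357156178e-06
28.101083864294871 8.9384959003339529e-06
28.818519864169918 1.3224576522475012e-05
29.554272396474897 1.9367914553333485e-05
30.308809092274206 2.8078099243968784e-05
31.082609521508406 4.0293621902310515e-05
31.876165497800244 5.7238555724081542e-05
32.689981391042501 8.0486822912963305e-05
33.524574447966486 0.00011203266327706027
34.380475120894701 0.00015436480681357948
35.25822740488681 0.00021054051698874858
36.15838918349305 0.00028425416322067098
37.081532583335047 0.00037989339351058985
38.028244337739174 0.00050257444976004137
38.999126159653656 0.00065814688244284945
39.994795124086544 0.00085315709906697435
41.015884060307442 0.0010947600660607196
42.063041954062363 0.0013905693194944287
43.136934360057502 0.0017484374378564217
44.238243824973708 0.0021761624331244384
45.367670321280947 0.0026811201611050394
46.525931692128125 0.003269828733113816
47.713764107591345 0.0039474577556111307
48.931922532570333 0.0047173025818285311
50.181181206630505 0.0055802510127470114
51.462334136095748 0.0065342762867724646
52.77619559870449 0.0075739949322967907
54.12360066115005 0.0086903303248553505
55.505405709833838 0.0098703219056040549
56.922488995169431 0.011097115513657475
58.375751189782306 0.012350162007103474
59.866115960961537 0.013605639523548095
61.394530557725901 0.014837100000907943
62.961966412878326 0.01601632397852425
64.569419760431103 0.017114350588904238
66.217912268794322 0.018102633598909044
67.908491690129893 0.018954260980366594
69.642232526283834 0.01964516626427559
71.420236711720563 0.020155256025960515
73.243634313892414 0.020469379956702696
75.113584251490238 0.020578078218371654
77.031275031031228 0.020478054647895125
78.997925502252272 0.020172342783843389
81.0147856327889 0.019670153046717358
83.083137302632252 0.0189864118146694
85.204295118868856 0.01814102457901931
87.379607251221302 0.017157913926877901
89.61045628892056 0.016063897183139456
91.898260119454918 0.014887477034013538
94.24447282975369 0.013657620819874865
96.650585630378473 0.012402600518852058
99.118127803310216 0.011148956417891837
101.64866767393292 0.009920634234266739
104.24381360783315 0.0087383294784346699
106.90521503304825 0.007619055751283744
109.63456348841311 0.006575937017858146
112.43359369867187 0.0056182090683431591
115.30408467703738 0.0047514034163814662
118.24786085590054 0.0039776784519521529
121.26679324640628 0.0032962580052584823
124.3628006276347 0.002703936449729077
127.53785076614247 0.0021956116209187302
130.79396166663986 0.0017648114756631159
134.13320285459815 0.0014041867648540594
137.5576966916029 0.0011059492266934563
141.06961972428854 0.00086224217374714085
144.67120406771247 0.00066543722325176013
148.36473882404704 0.00050835684804410853
152.15257153749178 0.00038442712492383675
156.03710968633013 0.00028776841633163717
160.02082221307958 0.00021323377116765391
164.10624109370639 0.00015640571089136832
168.29596294690484 0.00011356198710131431
172.59265068446075 8.1620099081802761e-05
176.99903520375042 5.8069088619209575e-05
181.51791712345008 4.0895607131075002e-05
186.15216856355784 2.8509661967133846e-05
190.90473497086268 1.9673935071379921e-05
195.77863699101658 1.3439222908522012e-05
200.77697238840278 9.0874249841076939e-06
205.90291801501903 6.0826282981840077e-06
211.15973182962742 4.0301895739572753e-06
216.55075496845453 2.643281583314045e-06
222.07941386875731 1.7161100822852865e-06
227.74922244660499 1.1028859735177753e-06
233.56378433026077 7.0161657750884581e-07
239.52679515058327 4.4182758599786925e-07
245.64204488990273 2.7541625720043615e-07
251.91342029086576 1.6994565833915467e-07
258.34490732677909 1.0380405848667496e-07
264.94059373502165 6.2762805921712598e-08
271.70467161513801 3.756419848292861e-08
278.64144009326088 2.2255105624561848e-08
285.75530805455799 1.3051756141466243e-08
293.05079694544082 7.5769077504515581e-09
300.53254364731333 4.3541040823798839e-09
308.20530342369187 2.4767910570874208e-09
316.07395294256395 1.3946450612915307e-09
324.14349337591108 7.7735925484021402e-10
332.4190535783635 4.2890747127192308e-10
340.90589334700786 2.3425518225395577e-10
349.6094067644197 1.2664806561616739e-10
358.53512562704503 6.7778456161796707e-11
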