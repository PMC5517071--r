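months,p
1,0.9975556737651435
13,0.9482471369762678
25,0.8900557422622243
37,0.8299106836436712
49,0.7701488269314472
61,0.7119890404183289
73,0.6561381724547051
85,0.6030128682721837
97,0.5528464695210742
109,0.5057493360790247
121,0.46174652696247115
133,0.42080301440353757
145,0.3828413763195913
157,0.34775462525596956
169,0.31541572031283915
181,0.28568472161238345
193,0.25841421517247126
205,0.23345343760502169
217,0.21065140536124485
229,0.18985927147437662
241,0.1709320770805444
253,0.1537300258298647
265,0.1381193809349836
277,0.12397306354083049
289,0.11117101511541906
301,0.09960037420593956
313,0.0891555082035898
325,0.0797379330448851
337,0.07125614757495709
349,0.06362540427006004
361,0.056767433912627716
373,0.05061013844580868
385,0.04508726346288007
397,0.0401380594997761
409,0.03570693940922927
421,0.03174313753340648
433,0.02820037510254911
445,0.02503653522447689
457,0.022213349956490533
469,0.019696101236254166
480,0.017630463285448563
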