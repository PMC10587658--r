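age	q
 67	0.016116827884400053
 68	0.017796680606289472
 69	0.019649868722689590
 70	0.021693891133141352
 71	0.023947927957670090
 72	0.026432983041718816
 73	0.029172034171279781
 74	0.032190190307224698
 75	0.035514854779700400
 76	0.039175892923613120
 77	0.043205802067337040
 78	0.047639881089327263
 79	0.052516395909612101
 80	0.057876736261601613
 81	0.063765557869324030
 82	0.070230902710690102
 83	0.077324288354228221
 84	0.085100755393597405
 85	0.093618859755905670
 86	0.102940594121756712
 87	0.113131219878574885
 88	0.124258987969682710
 89	0.136394723769278414
 90	0.149611247823795979
 91	0.163982601130921002
 92	0.179583040836663432
 93	0.196485770177240671
 94	0.214761365658409087
 95	0.234475865478170120
 96	0.255688486851748165
 97	0.278448947156951565
 98	0.302794375818508210
 99	0.328745821862217791
100	1.000000000000000000
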