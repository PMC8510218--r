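"record_id","comp1_id","comp2_id","x1","x2","T_K","has_Cl","has_Br","y"
"R00001","HBA04","HBD04",0.5,0.5,283.15,0,0,1.04632
"R00002","HBA04","HBD04",0.5,0.5,293.15,0,0,1.04542
"R00003","HBA04","HBD04",0.5,0.5,303.15,0,0,1.03432
"R00004","HBA04","HBD04",0.5,0.5,363.15,0,0,1.00377
"R00005","HBA04","HBD04",0.5,0.5,373.15,0,0,1.00111
"R00006","HBA03","HBD03",0.666667,0.333333,323.15,0,0,1.15983
"R00007","HBA03","HBD03",0.666667,0.333333,333.15,0,0,1.15336
"R00008","HBA03","HBD03",0.666667,0.333333,353.15,0,0,1.15117
"R00009","HBA03","HBD03",0.666667,0.333333,363.15,0,0,1.13939
"R00010","HBA03","HBD03",0.666667,0.333333,373.15,0,0,1.13713
"R00011","HBA02","HBD02",0.666667,0.333333,303.15,1,0,1.14516
"R00012","HBA02","HBD02",0.666667,0.333333,313.15,1,0,1.13018
"R00013","HBA02","HBD02",0.666667,0.333333,333.15,1,0,1.13121
"R00014","HBA02","HBD02",0.666667,0.333333,343.15,1,0,1.13199
"R00015","HBA02","HBD02",0.666667,0.333333,373.15,1,0,1.10941
"R00016","HBA03","HBD04",0.5,0.5,293.15,0,0,1.05918
"R00017","HBA03","HBD04",0.5,0.5,313.15,0,0,1.05962
"R00018","HBA03","HBD04",0.5,0.5,323.15,0,0,1.04936
"R00019","HBA03","HBD04",0.5,0.5,353.15,0,0,1.03813
"R00020","HBA03","HBD04",0.5,0.5,373.15,0,0,1.02414
"R00021","HBA04","HBD04",0.666667,0.333333,283.15,0,0,1.10454
"R00022","HBA04","HBD04",0.666667,0.333333,293.15,0,0,1.10371
"R00023","HBA04","HBD04",0.666667,0.333333,333.15,0,0,1.07977
"R00024","HBA04","HBD04",0.666667,0.333333,343.15,0,0,1.07335
"R00025","HBA04","HBD04",0.666667,0.333333,353.15,0,0,1.0631
"R00026","HBA05","HBD04",0.5,0.5,303.15,1,0,1.05256
"R00027","HBA05","HBD04",0.5,0.5,313.15,1,0,1.04259
"R00028","HBA05","HBD04",0.5,0.5,343.15,1,0,1.04056
"R00029","HBA05","HBD04",0.5,0.5,353.15,1,0,1.02637
"R00030","HBA05","HBD04",0.5,0.5,373.15,1,0,1.01067
"R00031","HBA03","HBD02",0.666667,0.333333,283.15,0,0,1.17653
"R00032","HBA03","HBD02",0.666667,0.333333,333.15,0,0,1.14102
"R00033","HBA03","HBD02",0.666667,0.333333,353.15,0,0,1.12539
"R00034","HBA03","HBD02",0.666667,0.333333,363.15,0,0,1.1231
"R00035","HBA03","HBD02",0.666667,0.333333,373.15,0,0,1.12353
"R00036","HBA01","HBD01",0.666667,0.333333,303.15,1,0,1.13387
"R00037","HBA01","HBD01",0.666667,0.333333,313.15,1,0,1.13333
"R00038","HBA01","HBD01",0.666667,0.333333,323.15,1,0,1.12489
"R00039","HBA01","HBD01",0.666667,0.333333,353.15,1,0,1.10175
"R00040","HBA01","HBD01",0.666667,0.333333,363.15,1,0,1.10459
"R00041","HBA02","HBD01",0.5,0.5,293.15,1,0,1.13575
"R00042","HBA02","HBD01",0.5,0.5,303.15,1,0,1.11971
"R00043","HBA02","HBD01",0.5,0.5,323.15,1,0,1.10897
"R00044","HBA02","HBD01",0.5,0.5,333.15,1,0,1.10632
"R00045","HBA02","HBD01",0.5,0.5,343.15,1,0,1.11018
"R00046","HBA04","HBD01",0.5,0.5,293.15,0,0,1.16502
"R00047","HBA04","HBD01",0.5,0.5,303.15,0,0,1.16828
"R00048","HBA04","HBD01",0.5,0.5,313.15,0,0,1.15631
"R00049","HBA04","HBD01",0.5,0.5,333.15,0,0,1.14774
"R00050","HBA04","HBD01",0.5,0.5,343.15,0,0,1.1426
"R00051","HBA05","HBD01",0.5,0.5,293.15,1,0,1.16346
"R00052","HBA05","HBD01",0.5,0.5,303.15,1,0,1.15759
"R00053","HBA05","HBD01",0.5,0.5,313.15,1,0,1.15493
"R00054","HBA05","HBD01",0.5,0.5,333.15,1,0,1.14488
"R00055","HBA05","HBD01",0.5,0.5,353.15,1,0,1.14036
"R00056","HBA05","HBD03",0.5,0.5,283.15,1,0,1.19716
"R00057","HBA05","HBD03",0.5,0.5,313.15,1,0,1.16913
"R00058","HBA05","HBD03",0.5,0.5,323.15,1,0,1.1741
"R00059","HBA05","HBD03",0.5,0.5,333.15,1,0,1.16793
"R00060","HBA05","HBD03",0.5,0.5,373.15,1,0,1.15033
"R00061","HBA03","HBD04",0.666667,0.333333,293.15,0,0,1.09112
"R00062","HBA03","HBD04",0.666667,0.333333,333.15,0,0,1.06251
"R00063","HBA03","HBD04",0.666667,0.333333,343.15,0,0,1.05633
"R00064","HBA03","HBD04",0.666667,0.333333,363.15,0,0,1.05282
"R00065","HBA03","HBD04",0.666667,0.333333,373.15,0,0,1.04886
"R00066","HBA05","HBD01",0.666667,0.333333,283.15,1,0,1.16633
"R00067","HBA05","HBD01",0.666667,0.333333,293.15,1,0,1.16461
"R00068","HBA05","HBD01",0.666667,0.333333,303.15,1,0,1.16004
"R00069","HBA05","HBD01",0.666667,0.333333,353.15,1,0,1.13438
"R00070","HBA05","HBD01",0.666667,0.333333,363.15,1,0,1.12469
"R00071","HBA01","HBD01",0.5,0.5,283.15,1,0,1.15211
"R00072","HBA01","HBD01",0.5,0.5,293.15,1,0,1.13208
"R00073","HBA01","HBD01",0.5,0.5,343.15,1,0,1.12149
"R00074","HBA01","HBD01",0.5,0.5,363.15,1,0,1.11043
"R00075","HBA01","HBD01",0.5,0.5,373.15,1,0,1.11367
"R00076","HBA02","HBD04",0.5,0.5,293.15,1,0,1.06399
"R00077","HBA02","HBD04",0.5,0.5,313.15,1,0,1.05323
"R00078","HBA02","HBD04",0.5,0.5,333.15,1,0,1.04865
"R00079","HBA02","HBD04",0.5,0.5,343.15,1,0,1.04134
"R00080","HBA02","HBD04",0.5,0.5,353.15,1,0,1.03265
"R00081","HBA04","HBD02",0.5,0.5,293.15,0,0,1.15924
"R00082","HBA04","HBD02",0.5,0.5,313.15,0,0,1.15003
"R00083","HBA04","HBD02",0.5,0.5,333.15,0,0,1.13399
"R00084","HBA04","HBD02",0.5,0.5,353.15,0,0,1.13552
"R00085","HBA04","HBD02",0.5,0.5,373.15,0,0,1.11664
"R00086","HBA03","HBD03",0.5,0.5,283.15,0,0,1.20373
"R00087","HBA03","HBD03",0.5,0.5,293.15,0,0,1.20365
"R00088","HBA03","HBD03",0.5,0.5,303.15,0,0,1.19321
"R00089","HBA03","HBD03",0.5,0.5,313.15,0,0,1.18969
"R00090","HBA03","HBD03",0.5,0.5,323.15,0,0,1.19286
"R00091","HBA02","HBD03",0.5,0.5,283.15,1,0,1.20165
"R00092","HBA02","HBD03",0.5,0.5,293.15,1,0,1.19869
"R00093","HBA02","HBD03",0.5,0.5,323.15,1,0,1.19233
"R00094","HBA02","HBD03",0.5,0.5,333.15,1,0,1.17811
"R00095","HBA02","HBD03",0.5,0.5,343.15,1,0,1.17206
"R00096","HBA05","HBD04",0.666667,0.333333,293.15,1,0,1.07133
"R00097","HBA05","HBD04",0.666667,0.333333,303.15,1,0,1.06811
"R00098","HBA05","HBD04",0.666667,0.333333,313.15,1,0,1.05678
"R00099","HBA05","HBD04",0.666667,0.333333,323.15,1,0,1.05435
"R00100","HBA05","HBD04",0.666667,0.333333,373.15,1,0,1.02942
"R00101","HBA02","HBD04",0.666667,0.333333,283.15,1,0,1.07169
"R00102","HBA02","HBD04",0.666667,0.333333,323.15,1,0,1.05661
"R00103","HBA02","HBD04",0.666667,0.333333,333.15,1,0,1.05997
"R00104","HBA02","HBD04",0.666667,0.333333,343.15,1,0,1.05094
"R00105","HBA02","HBD04",0.666667,0.333333,373.15,1,0,1.02786
"R00106","HBA02","HBD01",0.666667,0.333333,303.15,1,0,1.1111
"R00107","HBA02","HBD01",0.666667,0.333333,313.15,1,0,1.1031
"R00108","HBA02","HBD01",0.666667,0.333333,323.15,1,0,1.09852
"R00109","HBA02","HBD01",0.666667,0.333333,343.15,1,0,1.0937
"R00110","HBA02","HBD01",0.666667,0.333333,363.15,1,0,1.08237
"R00111","HBA04","HBD01",0.666667,0.333333,293.15,0,0,1.19362
"R00112","HBA04","HBD01",0.666667,0.333333,323.15,0,0,1.17627
"R00113","HBA04","HBD01",0.666667,0.333333,333.15,0,0,1.16497
"R00114","HBA04","HBD01",0.666667,0.333333,343.15,0,0,1.16149
"R00115","HBA04","HBD01",0.666667,0.333333,363.15,0,0,1.14791
"R00116","HBA03","HBD01",0.5,0.5,283.15,0,0,1.1354
"R00117","HBA03","HBD01",0.5,0.5,303.15,0,0,1.1291
"R00118","HBA03","HBD01",0.5,0.5,313.15,0,0,1.1092
"R00119","HBA03","HBD01",0.5,0.5,323.15,0,0,1.1127
"R00120","HBA03","HBD01",0.5,0.5,353.15,0,0,1.09987
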