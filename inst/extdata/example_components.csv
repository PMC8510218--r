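"chemical_id","d01","d02","d03","d04","d05","d06"
"HBA01",0.0844,2.0594,-1.4032,-0.4974,-0.3878,-2.1452
"HBA02",-0.191,1.0651,-0.0036,-0.6599,0.3767,-3.0086
"HBA03",0.9044,0.5222,-0.1369,0.4016,-0.2003,-1.3639
"HBA04",0.3369,-0.8691,-1.3957,-0.2157,0.939,-2.668
"HBA05",0.4003,1.1649,-0.9538,-1.8209,0.5816,-2.1753
"HBD01",0.0889,-0.2212,-0.1409,-0.2332,0.0178,-3.3731
"HBD02",0.5807,0.002,-1.8375,-1.7487,0.6259,-3.0448
"HBD03",0.5765,-1.6684,-1.3142,-2.1079,0.4372,-1.7398
"HBD04",-1.6662,2.2211,-1.6311,-0.0162,-0.3704,-3.0902
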