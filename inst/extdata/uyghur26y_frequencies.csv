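locus,allele,frequency,count
DYS19,13,0.0990,10
DYS19,14,0.2673,27
DYS19,15,0.4356,44
DYS19,16,0.1089,11
DYS19,17,0.0891,9
DYS389I,12,0.1600,16
DYS389I,13,0.4700,47
DYS389I,14,0.3600,36
DYS389I,15,0.0100,1
DYS389II,27,0.0200,2
DYS389II,28,0.1000,10
DYS389II,29,0.2800,28
DYS389II,30,0.3300,33
DYS389II,31,0.1800,18
DYS389II,32,0.0900,9
DYS390,19,0.0300,3
DYS390,20,0.0100,1
DYS390,21,0.0000,0
DYS390,22,0.0700,7
DYS390,23,0.3200,32
DYS390,24,0.2900,29
DYS390,25,0.2500,25
DYS390,26,0.0300,3
DYS391,9,0.0300,3
DYS391,10,0.6200,62
DYS391,11,0.3500,35
DYS392,7,0.0500,5
DYS392,10,0.0200,2
DYS392,11,0.4600,46
DYS392,12,0.0200,2
DYS392,13,0.2300,23
DYS392,14,0.1700,17
DYS392,15,0.0300,3
DYS392,16,0.0200,2
DYS393,11,0.0100,1
DYS393,12,0.3400,34
DYS393,13,0.5300,53
DYS393,14,0.1000,10
DYS393,15,0.0200,2
DYS385ab,9,0.0108,2
DYS385ab,10,0.0054,1
DYS385ab,11,0.2043,38
DYS385ab,12,0.1022,19
DYS385ab,13,0.1505,28
DYS385ab,14,0.1882,35
DYS385ab,15,0.0860,16
DYS385ab,16,0.0860,16
DYS385ab,17,0.0699,13
DYS385ab,18,0.0323,6
DYS385ab,19,0.0108,2
DYS385ab,20,0.0323,6
DYS385ab,21,0.0108,2
DYS385ab,22,0.0054,1
DYS385ab,24,0.0054,1
DYS437,13,0.0300,3
DYS437,14,0.5700,57
DYS437,15,0.3300,33
DYS437,16,0.0700,7
DYS438,9,0.0800,8
DYS438,10,0.4100,41
DYS438,11,0.4000,40
DYS438,12,0.1000,10
DYS438,13,0.0100,1
DYS439,10,0.3000,30
DYS439,11,0.2400,24
DYS439,12,0.3200,32
DYS439,13,0.1200,12
DYS439,14,0.0200,2
DYS448,16,0.0100,1
DYS448,18,0.0800,8
DYS448,19,0.4200,42
DYS448,20,0.3700,37
DYS448,21,0.0900,9
DYS448,22,0.0200,2
DYS448,null,0.0100,1
DYS456,13,0.0100,1
DYS456,14,0.1300,13
DYS456,15,0.5500,55
DYS456,16,0.2200,22
DYS456,17,0.0700,7
DYS456,18,0.0200,2
DYS458,14,0.0400,4
DYS458,15,0.2800,28
DYS458,16,0.2000,20
DYS458,17,0.1900,19
DYS458,18,0.1700,17
DYS458,19,0.0500,5
DYS458,20,0.0600,6
DYS458,21,0.0100,1
DYS635,19,0.0500,5
DYS635,20,0.0700,7
DYS635,21,0.2900,29
DYS635,22,0.2000,20
DYS635,23,0.2800,28
DYS635,24,0.0900,9
DYS635,26,0.0100,1
DYS635,27,0.0100,1
Y_GATA_H4,10,0.0600,6
Y_GATA_H4,11,0.4200,42
Y_GATA_H4,12,0.3400,34
Y_GATA_H4,13,0.1700,17
Y_GATA_H4,14,0.0100,1
DYS576,13,0.0100,1
DYS576,14,0.0100,1
DYS576,15,0.0200,2
DYS576,16,0.1200,12
DYS576,17,0.2700,27
DYS576,18,0.3300,33
DYS576,19,0.1700,17
DYS576,20,0.0600,6
DYS576,21,0.0100,1
DYS570,13,0.0100,1
DYS570,14,0.0200,2
DYS570,15,0.0100,1
DYS570,16,0.1400,14
DYS570,17,0.2400,24
DYS570,18,0.2100,21
DYS570,19,0.2200,22
DYS570,20,0.1100,11
DYS570,21,0.0300,3
DYS570,24,0.0100,1
DYS481,19,0.0100,1
DYS481,20,0.0400,4
DYS481,21,0.0500,5
DYS481,22,0.1200,12
DYS481,23,0.2600,26
DYS481,24,0.2100,21
DYS481,25,0.2100,21
DYS481,26,0.0600,6
DYS481,27,0.0300,3
DYS481,28,0.0100,1
DYS533,9,0.0100,1
DYS533,10,0.0700,7
DYS533,11,0.3400,34
DYS533,12,0.4900,49
DYS533,13,0.0800,8
DYS533,14,0.0100,1
DYS549,10,0.0100,1
DYS549,11,0.1000,10
DYS549,12,0.4800,48
DYS549,13,0.2900,29
DYS549,14,0.1000,10
DYS549,15,0.0200,2
DYS643,8,0.0400,4
DYS643,9,0.1300,13
DYS643,10,0.4400,44
DYS643,11,0.2500,25
DYS643,12,0.1100,11
DYS643,13,0.0100,1
DYS643,14,0.0100,1
DYS643,null,0.0100,1
DYS460,9,0.1400,14
DYS460,10,0.3500,35
DYS460,11,0.4600,46
DYS460,12,0.0500,5
DYS449,25,0.0099,1
DYS449,26,0.0198,2
DYS449,27,0.0495,5
DYS449,28,0.0297,3
DYS449,29,0.1089,11
DYS449,30,0.1485,15
DYS449,31,0.1980,20
DYS449,32,0.2673,27
DYS449,33,0.1089,11
DYS449,34,0.0297,3
DYS449,34.1,0.0099,1
DYS449,35,0.0198,2
DYS388,10,0.0300,3
DYS388,12,0.7900,79
DYS388,13,0.0600,6
DYS388,14,0.0900,9
DYS388,15,0.0200,2
DYS388,16,0.0100,1
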