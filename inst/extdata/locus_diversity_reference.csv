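locus,population,na,ho,he
Fca8,PO_wild,7,0.78,0.75
Fca45,PO_wild,5,0.67,0.70
Fca58,PO_wild,4,0.33,0.29
Fca96,PO_wild,7,1.00,0.80
Fca124,PO_wild,7,0.88,0.82
Fca126,PO_wild,6,0.67,0.73
Fca577,PO_wild,4,0.64,0.63
Fca668,PO_wild,4,0.82,0.69
Fca675,PO_wild,10,1.00,0.88
Fca26,PO_wild,9,1.00,0.85
Fca069,PO_wild,7,1.00,0.81
Fca075,PO_wild,8,1.00,0.79
Fca105,PO_wild,10,1.00,0.88
Fca149,PO_wild,8,1.00,0.83
Fca201,PO_wild,7,1.00,0.76
Fca220,PO_wild,6,1.00,0.71
Fca229,PO_wild,9,1.00,0.80
Fca293,PO_wild,5,1.00,0.75
Fca310,PO_wild,3,1.00,0.62
Fca441,PO_wild,4,1.00,0.63
Fca453,PO_wild,4,1.00,0.63
Fca678,PO_wild,5,1.00,0.72
Fca8,NE_wild,7.30,0.76,0.80
Fca45,NE_wild,6.57,0.78,0.74
Fca58,NE_wild,5.83,0.59,0.48
Fca96,NE_wild,8.93,0.39,0.84
Fca124,NE_wild,7.70,0.76,0.79
Fca126,NE_wild,6.23,0.49,0.73
Fca577,NE_wild,5.70,0.70,0.49
Fca668,NE_wild,6.07,0.83,0.67
Fca675,NE_wild,10.10,1.00,0.86
Fca26,NE_wild,12.10,1.00,0.89
Fca069,NE_wild,9.93,1.00,0.84
Fca075,NE_wild,10.87,1.00,0.87
Fca105,NE_wild,11.10,1.00,0.87
Fca149,NE_wild,8.63,1.00,0.79
Fca201,NE_wild,9.37,1.00,0.85
Fca220,NE_wild,9.27,1.00,0.84
Fca229,NE_wild,11.03,1.00,0.87
Fca293,NE_wild,7.20,1.00,0.75
Fca310,NE_wild,4.93,1.00,0.70
Fca441,NE_wild,5.67,1.00,0.69
Fca453,NE_wild,6.87,1.00,0.81
Fca678,NE_wild,4.63,0.95,0.69
Fca8,PO_domestic,6.80,0.85,0.80
Fca45,PO_domestic,7.90,0.71,0.79
Fca58,PO_domestic,6.00,0.90,0.78
Fca96,PO_domestic,5.53,0.45,0.46
Fca124,PO_domestic,6.87,0.85,0.79
Fca126,PO_domestic,9.80,0.77,0.86
Fca577,PO_domestic,6.77,0.69,0.77
Fca668,PO_domestic,5.80,0.71,0.71
Fca675,PO_domestic,10.33,1.00,0.82
Fca26,PO_domestic,10.80,1.00,0.88
Fca069,PO_domestic,9.77,1.00,0.84
Fca075,PO_domestic,10.60,1.00,0.83
Fca105,PO_domestic,8.67,1.00,0.79
Fca149,PO_domestic,8.90,1.00,0.84
Fca201,PO_domestic,10.70,1.00,0.87
Fca220,PO_domestic,9.83,1.00,0.82
Fca229,PO_domestic,7.63,1.00,0.79
Fca293,PO_domestic,8.00,1.00,0.84
Fca310,PO_domestic,7.70,1.00,0.77
Fca441,PO_domestic,8.00,1.00,0.86
Fca453,PO_domestic,7.57,1.00,0.81
Fca678,PO_domestic,7.73,0.95,0.78
Fca8,NE_domestic,8.90,0.76,0.83
Fca45,NE_domestic,9.87,0.78,0.83
Fca58,NE_domestic,6.50,0.59,0.67
Fca96,NE_domestic,6.07,0.39,0.43
Fca124,NE_domestic,7.20,0.76,0.75
Fca126,NE_domestic,5.27,0.49,0.56
Fca577,NE_domestic,7.50,0.70,0.76
Fca668,NE_domestic,9.27,0.83,0.84
Fca675,NE_domestic,9.00,1.00,0.83
Fca26,NE_domestic,13.20,1.00,0.88
Fca069,NE_domestic,11.83,1.00,0.87
Fca075,NE_domestic,10.43,1.00,0.82
Fca105,NE_domestic,10.93,1.00,0.86
Fca149,NE_domestic,12.57,1.00,0.88
Fca201,NE_domestic,9.87,1.00,0.85
Fca220,NE_domestic,10.67,1.00,0.80
Fca229,NE_domestic,9.77,1.00,0.80
Fca293,NE_domestic,10.27,1.00,0.85
Fca310,NE_domestic,8.60,1.00,0.78
Fca441,NE_domestic,8.53,1.00,0.83
Fca453,NE_domestic,8.03,1.00,0.81
Fca678,NE_domestic,6.77,0.95,0.79
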