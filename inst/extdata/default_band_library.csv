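component,center,width,amplitude
palmitic,720,10,0.18
palmitic,1112,10,0.12
palmitic,1465,12,0.32
palmitic,1745,14,0.8
palmitic,1160,16,0.5
palmitic,2855,14,0.6
palmitic,2925,16,0.85
stearic,730,10,0.2
stearic,1300,10,0.1
stearic,1465,12,0.34
stearic,1745,14,0.78
stearic,1160,16,0.48
stearic,2855,14,0.66
stearic,2925,16,0.92
oleic,1465,12,0.28
oleic,1655,12,0.05
oleic,1745,14,0.76
oleic,1160,16,0.46
oleic,2855,14,0.55
oleic,2925,16,0.8
oleic,3005,12,0.12
elaidic,966,10,0.35
elaidic,1670,12,0.04
elaidic,1745,14,0.76
elaidic,1160,16,0.46
elaidic,2855,14,0.55
elaidic,2920,16,0.8
elaidic,3000,12,0.12
linoleic,1099,10,0.15
linoleic,1652,12,0.09
linoleic,1745,14,0.75
linoleic,1160,16,0.45
linoleic,2855,14,0.52
linoleic,2925,16,0.78
linoleic,3008,12,0.24
alpha_linolenic,914,10,0.18
alpha_linolenic,1650,12,0.12
alpha_linolenic,1745,14,0.74
alpha_linolenic,1160,16,0.44
alpha_linolenic,2855,14,0.5
alpha_linolenic,2925,16,0.76
alpha_linolenic,3012,12,0.36
unsaponifiable,1050,18,0.25
unsaponifiable,1600,16,0.15
unsaponifiable,2935,18,0.2
unsaponifiable,3450,45,0.3
hydroperoxide,830,12,0.1
hydroperoxide,3430,45,0.25
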