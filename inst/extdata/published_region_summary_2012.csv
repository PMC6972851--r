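region,land_area_mil_ha,extent_pct_treated,intensity_contact_bil_per_treated_ha,intensity_oral_bil_per_treated_ha,load_contact_bil_per_ha,load_oral_bil_per_ha
Basin and Range,163,0.5,5,8,0.02,0.04
Eastern Uplands,52,1.6,4,14,0.07,0.23
Fruitful Rim,124,3.8,10,18,0.4,0.68
Heartland,73,20.2,4,21,0.79,4.22
Mississippi Portal,26,14.1,5,10,0.71,1.48
Northern Crescent,82,4.3,5,16,0.22,0.70
Northern Great Plains,75,5.6,4,12,0.23,0.68
Prairie Gateway,107,4.8,5,15,0.25,0.72
Southern Seaboard,64,4.8,7,9,0.34,0.46
Contiguous US,765,5.3,5,16,0.28,0.87
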