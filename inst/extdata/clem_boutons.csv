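axon,bouton_id,weight,p_bouton,volume_um3,mito_volume_um3,psd_area_um2
1,1,13.5,1.00,0.919,0.189,0.666
1,2,10.8,1.00,0.779,0.170,0.595
1,3,1.98,0.48,0.093,NA,0.371
1,4,10.1,1.00,0.998,0.225,1.92
1,5,8.65,1.00,0.669,0.139,1.83
1,6,6.25,1.00,0.219,0.043,0.138
2,7,3.63,0.93,0.483,0.111,0.612
2,8,NA,NA,0.574,NA,2.75
2,9,5.57,1.00,0.372,0.027,1.28
3,10,9.54,1.00,0.632,0.182,0.645
3,11,1.99,0.49,0.102,NA,NA
3,12,8.51,1.00,0.456,NA,1.23
3,13,10.8,1.00,0.704,0.161,1.49
4,14,5.80,1.00,0.308,NA,0.867
4,15,4.23,1.00,0.198,NA,0.686
4,16,5.96,1.00,0.229,0.027,0.402
4,17,2.85,0.93,0.140,NA,NA
4,18,1.14,0.01,NA,NA,NA
4,19,2.19,0.65,NA,NA,NA
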