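country,lon,lat,area_y1_mha,area_y2_mha
Ukraine,31.00,48.00,4.10,3.90
Romania,26.10,44.40,2.43,2.57
France,1.90,46.60,1.45,1.51
Italy,9.20,45.10,1.18,1.24
Hungary,19.50,47.10,1.02,1.08
Serbia,20.80,44.00,0.98,0.96
Germany,10.40,51.10,0.82,0.78
Poland,21.00,52.20,0.74,0.76
Spain,-3.70,40.20,0.68,0.72
Bulgaria,25.50,42.70,0.55,0.57
Austria,14.60,47.50,0.50,0.54
Croatia,16.00,45.10,0.28,0.32
Slovakia,19.70,48.70,0.15,0.15
Greece,22.30,39.10,0.15,0.17
Czechia,15.47,49.82,0.08,0.10
Netherlands,5.55,52.37,0.08,0.06
Belgium,4.47,50.85,0.06,0.06
Portugal,-8.20,39.50,0.12,0.10
United Kingdom,0.10,52.30,0.02,0.02
Sweden,18.10,59.30,0.01,0.01
Finland,25.70,61.90,0.00,0.00
Norway,8.50,60.40,0.00,0.00
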