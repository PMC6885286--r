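"angle_deg","energy_kcal_mol"
-180,0
-170,0.156085734480956
-160,0.605996474927489
-150,1.29689110867545
-140,2.14776400074103
-130,3.05914478077704
-120,3.925
-110,4.64540405763346
-100,5.13845468978135
-90,5.35
-80,5.2600084141482
-70,4.88481815796143
-60,4.275
-50,3.50909610755761
-40,2.68399511092432
-30,1.90310889132455
-20,1.26378130947762
-10,0.845451161589502
0,0.7
10,0.845451161589502
20,1.26378130947762
30,1.90310889132455
40,2.68399511092432
50,3.50909610755761
60,4.275
70,4.88481815796143
80,5.2600084141482
90,5.35
100,5.13845468978135
110,4.64540405763346
120,3.925
130,3.05914478077704
140,2.14776400074103
150,1.29689110867545
160,0.605996474927487
170,0.156085734480956
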