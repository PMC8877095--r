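bowl,quantity,actual,calculated,reported_error_pct
1,diameter_mm,101,96.9,-4.1
2,diameter_mm,110,110.6,0.5
3,diameter_mm,121,118.7,-1.9
4,diameter_mm,157,154.6,-1.5
5,diameter_mm,153,154.3,0.8
6,diameter_mm,135,135.2,0.1
7,diameter_mm,151,142.7,-5.5
8,diameter_mm,152,145.4,-4.3
9,diameter_mm,143,135.6,-5.2
1,depth_mm,45,47.3,5.1
2,depth_mm,42,39.1,-6.9
3,depth_mm,52,52.5,1.0
4,depth_mm,44,42.2,-4.1
5,depth_mm,43,42.9,-0.2
6,depth_mm,70,67.9,-3.0
7,depth_mm,59,62.3,5.6
8,depth_mm,61,64.1,5.1
9,depth_mm,65,68.7,5.7
1,capacity_ml,288,288.7,0.2
2,capacity_ml,291,288.0,-1.0
3,capacity_ml,371,362.9,-2.2
4,capacity_ml,500,496.9,-0.6
5,capacity_ml,500,553.0,10.6
6,capacity_ml,642,661.4,3.0
7,capacity_ml,773,769.4,-0.5
8,capacity_ml,787,803.4,2.1
9,capacity_ml,810,851.6,5.1
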