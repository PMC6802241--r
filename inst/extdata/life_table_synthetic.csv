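"sex","age","q"
"male",0,0.000311479207066534
"male",1,0.000322108950147282
"male",2,0.000333566527495388
"male",3,0.000345916405501412
"male",4,0.000359228070044293
"male",5,0.000373576417201482
"male",6,0.00038904217434943
"male",7,0.000405712354020316
"male",8,0.000423680743053878
"male",9,0.000443048429791038
"male",10,0.000463924372256952
"male",11,0.000486426010520402
"male",12,0.000510679926652768
"male",13,0.000536822555981864
"male",14,0.000565000953617001
"male",15,0.000595373620531414
"male",16,0.000628111393817021
"male",17,0.000663398406079652
"male",18,0.000701433119333683
"male",19,0.000742429439158143
"male",20,0.000786617915322529
"male",21,0.000834247035571223
"male",22,0.000885584619761959
"male",23,0.00094091932210838
"male",24,0.001000562249871
"male",25,0.0010648487074727
"male",26,0.00113414007570822
"male",27,0.00120882583644277
"male",28,0.00128932575399465
"male",29,0.00137609222524049
"male",30,0.00146961281139135
"male",31,0.00157041296537419
"male",32,0.00167905896978915
"male",33,0.00179616110155367
"male",34,0.00192237704053422
"male",35,0.00205841554077502
"male",36,0.00220504038429914
"male",37,0.0023630746389548
"male",38,0.00253340524335233
"male",39,0.00271698794363395
"female",0,0.000178
"female",1,0.000184074963769001
"female",2,0.000190623070932806
"female",3,0.000197681171862965
"female",4,0.000205288986990928
"female",5,0.00021348933034022
"female",6,0.000222328350468233
"female",7,0.000231855790173569
"female",8,0.00024212526643046
"female",9,0.000253194572125648
"female",10,0.000265126001295789
"female",11,0.000277986699695686
"female",12,0.000291849042670242
"female",13,0.000306791042456643
"female",14,0.000322896787208927
"female",15,0.000340256914215606
"female",16,0.000358969119973451
"female",17,0.000379138709987923
"female",18,0.000400879191394364
"female",19,0.000424312911734969
"female",20,0.000449571747486369
"female",21,0.000476797846212602
"female",22,0.000506144426520028
"female",23,0.000537776640316066
"female",24,0.00057187250222421
"female",25,0.000608623891385749
"female",26,0.000648237631285965
"female",27,0.000690936653681674
"female",28,0.000736961253180277
"female",29,0.000786570439530633
"female",30,0.000840043395235965
"female",31,0.000897681046691698
"female",32,0.000959807757690045
"female",33,0.00102677315482175
"female",34,0.00109895409504772
"female",35,0.00117675678651323
"female",36,0.00126061907454008
"female",37,0.00135101290566114
"female",38,0.00144844698356428
"female",39,0.00155346963189212
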