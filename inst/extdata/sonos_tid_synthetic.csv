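"weight","dose_krad","mu","sigma"
-1,0,0,0.02
-0.75,0,0,0.02
-0.5,0,0,0.02
-0.25,0,0,0.02
0,0,0,0.02
0.25,0,0,0.02
0.5,0,0,0.02
0.75,0,0,0.02
1,0,0,0.02
-1,100,0.221199216928595,0.0310599608464298
-0.75,100,0.165899412696446,0.029677465740626
-0.5,100,0.110599608464298,0.0282949706348223
-0.25,100,0.0552998042321488,0.0269124755290186
0,100,0,0.0255299804232149
0.25,100,-0.0552998042321488,0.0269124755290186
0.5,100,-0.110599608464298,0.0282949706348223
0.75,100,-0.165899412696446,0.029677465740626
1,100,-0.221199216928595,0.0310599608464298
-1,200,0.393469340287367,0.0396734670143683
-0.75,200,0.295102005215525,0.0372142836375723
-0.5,200,0.196734670143683,0.0347551002607762
-0.25,200,0.0983673350718416,0.0322959168839802
0,200,0,0.0298367335071842
0.25,200,-0.0983673350718416,0.0322959168839802
0.5,200,-0.196734670143683,0.0347551002607762
0.75,200,-0.295102005215525,0.0372142836375723
1,200,-0.393469340287367,0.0396734670143683
-1,300,0.527633447258985,0.0463816723629493
-0.75,300,0.395725085444239,0.0430839633175806
-0.5,300,0.263816723629493,0.039786254272212
-0.25,300,0.131908361814746,0.0364885452268433
0,300,0,0.0331908361814746
0.25,300,-0.131908361814746,0.0364885452268433
0.5,300,-0.263816723629493,0.039786254272212
0.75,300,-0.395725085444239,0.0430839633175806
1,300,-0.527633447258985,0.0463816723629493
-1,400,0.632120558828558,0.0516060279414279
-0.75,400,0.474090419121418,0.0476552744487494
-0.5,400,0.316060279414279,0.0437045209560709
-0.25,400,0.158030139707139,0.0397537674633924
0,400,0,0.0358030139707139
0.25,400,-0.158030139707139,0.0397537674633924
0.5,400,-0.316060279414279,0.0437045209560709
0.75,400,-0.474090419121418,0.0476552744487494
1,400,-0.632120558828558,0.0516060279414279
-1,500,0.71349520313981,0.0556747601569905
-0.75,500,0.535121402354857,0.0512154151373667
-0.5,500,0.356747601569905,0.0467560701177429
-0.25,500,0.178373800784952,0.0422967250981191
0,500,0,0.0378373800784952
0.25,500,-0.178373800784952,0.0422967250981191
0.5,500,-0.356747601569905,0.0467560701177429
0.75,500,-0.535121402354857,0.0512154151373667
1,500,-0.71349520313981,0.0556747601569905
-1,600,0.77686983985157,0.0588434919925785
-0.75,600,0.582652379888678,0.0539880554935062
-0.5,600,0.388434919925785,0.0491326189944339
-0.25,600,0.194217459962893,0.0442771824953616
0,600,0,0.0394217459962893
0.25,600,-0.194217459962893,0.0442771824953616
0.5,600,-0.388434919925785,0.0491326189944339
0.75,600,-0.582652379888678,0.0539880554935062
1,600,-0.77686983985157,0.0588434919925785
-1,700,0.826226056549555,0.0613113028274778
-0.75,700,0.619669542412166,0.056147389974043
-0.5,700,0.413113028274777,0.0509834771206083
-0.25,700,0.206556514137389,0.0458195642671736
0,700,0,0.0406556514137389
0.25,700,-0.206556514137389,0.0458195642671736
0.5,700,-0.413113028274777,0.0509834771206083
0.75,700,-0.619669542412166,0.056147389974043
1,700,-0.826226056549555,0.0613113028274778
-1,800,0.864664716763387,0.0632332358381694
-0.75,800,0.648498537572541,0.0578290813583982
-0.5,800,0.432332358381694,0.052424926878627
-0.25,800,0.216166179190847,0.0470207723988559
0,800,0,0.0416166179190847
0.25,800,-0.216166179190847,0.0470207723988559
0.5,800,-0.432332358381694,0.052424926878627
0.75,800,-0.648498537572541,0.0578290813583982
1,800,-0.864664716763387,0.0632332358381694
-1,900,0.894600775438136,0.0647300387719068
-0.75,900,0.670950581578602,0.0591387839254184
-0.5,900,0.447300387719068,0.0535475290789301
-0.25,900,0.223650193859534,0.0479562742324417
0,900,0,0.0423650193859534
0.25,900,-0.223650193859534,0.0479562742324417
0.5,900,-0.447300387719068,0.0535475290789301
0.75,900,-0.670950581578602,0.0591387839254184
1,900,-0.894600775438136,0.0647300387719068
-1,1000,0.917915001376101,0.0658957500688051
-0.75,1000,0.688436251032076,0.0601587813102044
-0.5,1000,0.458957500688051,0.0544218125516038
-0.25,1000,0.229478750344025,0.0486848437930032
0,1000,0,0.0429478750344025
0.25,1000,-0.229478750344025,0.0486848437930032
0.5,1000,-0.458957500688051,0.0544218125516038
0.75,1000,-0.688436251032076,0.0601587813102044
1,1000,-0.917915001376101,0.0658957500688051
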