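genet_id,site,taxon,c_event1,c_event2,delta,response,survived_full,area_first,area_last,area_2015,area_2019
1,North,Encruster,5,5,0,high_susceptibility,TRUE,135.017571197795,130.820768381933,93.5977416515557,117.108270914918
2,North,Encruster,1,5,4,increased,TRUE,45.7904055798151,42.011746045427,34.3105632748245,39.4095903266831
4,North,Encruster,4,2,-2,decreased,TRUE,335.470177796435,344.109324426008,483.684029284099,369.40121513117
5,North,Encruster,4,1,-3,decreased,TRUE,124.694846050735,83.3596246037168,123.550219380537,126.148477374005
6,North,Encruster,1,5,4,increased,TRUE,255.823031151084,493.27325715625,283.577590487399,409.427181327376
7,North,Encruster,2,1,-1,thermally_tolerant,TRUE,4126.9928409865,23861.6773131587,4294.92983703626,10314.2265637689
8,North,Encruster,1,2,1,thermally_tolerant,TRUE,25.1724153347301,101.397729201678,25.6467477068193,55.0948472409916
10,North,Encruster,4,1,-3,decreased,TRUE,62.7283309810446,65.0041317241217,64.3249759468304,82.6382320973619
11,North,Encruster,3,1,-2,decreased,TRUE,131.297143354968,150.20278500141,170.696033533415,117.075701002077
12,North,Encruster,3,1,-2,decreased,TRUE,193.348856124065,262.765991330948,215.21676332997,219.54695812691
13,North,Encruster,3,4,1,high_susceptibility,TRUE,106.853157118381,359.312712079834,156.800369310982,256.885619307272
14,North,Encruster,1,4,3,increased,TRUE,58.6711787650069,160.696205241141,109.113615430785,205.530972697659
15,North,Encruster,1,1,0,thermally_tolerant,TRUE,34.2943445166856,48.039333674246,42.6879290109643,64.9221209878243
20,North,Brancher,3,4,1,high_susceptibility,TRUE,47.9720112780313,143.632848005903,54.8956734431035,118.608151716858
22,North,Brancher,4,5,1,high_susceptibility,TRUE,7.23687218684221,10.8585168377167,6.31923955468453,8.54984093506085
29,North,Brancher,4,4,0,high_susceptibility,TRUE,366.521840279936,265.181984299126,391.539440245164,195.184640031145
31,South,Encruster,1,2,1,thermally_tolerant,TRUE,64.0625905957351,135.536200158572,78.7764316409664,131.610035389794
32,South,Encruster,5,1,-4,decreased,TRUE,17.8815221124998,66.5568819557979,20.3163361653208,42.9105585164046
33,South,Encruster,4,1,-3,decreased,TRUE,73.874916898383,49.3124274677333,105.374419397822,43.0774668246146
34,South,Encruster,1,1,0,thermally_tolerant,TRUE,124.34406181519,265.068670115629,176.60135276459,223.526724739606
35,South,Encruster,2,4,2,increased,TRUE,43.135037012316,104.852377059746,56.4076386117548,69.4123384227668
36,South,Encruster,3,3,0,high_susceptibility,TRUE,124.166758731951,95.9654617973937,103.756411260228,155.54435520489
37,South,Encruster,4,2,-2,decreased,TRUE,24.0419962386559,21.4197204676172,26.1602849430586,22.3089867725104
38,South,Encruster,5,3,-2,decreased,TRUE,261.395402885289,395.992496522885,336.027373720208,370.534607661355
39,South,Encruster,4,1,-3,decreased,TRUE,26.2821718088159,25.1524664055372,14.8701878152794,28.1975634420689
40,South,Encruster,1,2,1,thermally_tolerant,TRUE,1974.7316131492,799.804162395657,1365.73271299223,982.589589728927
41,South,Encruster,3,1,-2,decreased,TRUE,7.23032633849913,12.1888814227894,7.10770090958264,10.9668658954647
42,South,Encruster,2,1,-1,thermally_tolerant,TRUE,304.607238571747,560.367358864752,414.762764043076,564.064523901671
43,South,Encruster,4,1,-3,decreased,TRUE,121.312083440533,96.970090700191,106.478939670321,98.7138759667696
44,South,Encruster,3,1,-2,decreased,TRUE,27.2089666930937,48.7184527615428,18.858767478189,31.3780651941828
45,South,Encruster,4,1,-3,decreased,TRUE,127.33632846653,152.105337713353,147.151778683721,192.766280855896
47,South,Brancher,5,1,-4,decreased,FALSE,141.847066952804,0,163.808074672876,170.185280885143
48,South,Brancher,4,1,-3,decreased,FALSE,43.8816443720544,0,79.6379550242062,105.788576175483
51,South,Brancher,3,4,1,high_susceptibility,FALSE,277.057283490947,0,178.886938348812,351.93520430085
53,South,Brancher,5,5,0,high_susceptibility,FALSE,93.7571052579358,0,111.006230360612,154.085353925948
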