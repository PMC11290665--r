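genet_id,site,taxon,first_year,last_year,survived,area_2014,area_2015,area_2017,area_2019,area_2021
1,North,Encruster,2014,2021,TRUE,135.017571197795,93.5977416515557,129.136989967477,117.108270914918,130.820768381933
2,North,Encruster,2014,2021,TRUE,45.7904055798151,34.3105632748245,61.5198175295898,39.4095903266831,42.011746045427
3,North,Encruster,2014,2015,FALSE,31.798799281711,40.2045976847924,0,0,0
4,North,Encruster,2014,2021,TRUE,335.470177796435,483.684029284099,520.655859987004,369.40121513117,344.109324426008
5,North,Encruster,2014,2021,TRUE,124.694846050735,123.550219380537,159.821299145497,126.148477374005,83.3596246037168
6,North,Encruster,2014,2021,TRUE,255.823031151084,283.577590487399,310.000347452136,409.427181327376,493.27325715625
7,North,Encruster,2014,2021,TRUE,4126.9928409865,4294.92983703626,5785.11551821907,10314.2265637689,23861.6773131587
8,North,Encruster,2014,2021,TRUE,25.1724153347301,25.6467477068193,43.9076075138361,55.0948472409916,101.397729201678
9,North,Encruster,2014,2015,FALSE,248.139715695247,321.817992569181,0,0,0
10,North,Encruster,2014,2021,TRUE,62.7283309810446,64.3249759468304,92.4442547211289,82.6382320973619,65.0041317241217
11,North,Encruster,2014,2021,TRUE,131.297143354968,170.696033533415,141.797857124382,117.075701002077,150.20278500141
12,North,Encruster,2014,2021,TRUE,193.348856124065,215.21676332997,178.115394207946,219.54695812691,262.765991330948
13,North,Encruster,2014,2021,TRUE,106.853157118381,156.800369310982,170.822950589968,256.885619307272,359.312712079834
14,North,Encruster,2014,2021,TRUE,58.6711787650069,109.113615430785,112.750341098657,205.530972697659,160.696205241141
15,North,Encruster,2014,2021,TRUE,34.2943445166856,42.6879290109643,54.6721383439494,64.9221209878243,48.039333674246
16,North,Brancher,2014,2014,FALSE,88.6456510643957,0,0,0,0
17,North,Brancher,2014,2017,FALSE,40.0297383565157,79.7596522593011,47.4139827382128,0,0
18,North,Brancher,2014,2014,FALSE,44.8361771671796,0,0,0,0
19,North,Brancher,2014,2015,FALSE,189.544523790653,201.060016921945,0,0,0
20,North,Brancher,2014,2021,TRUE,47.9720112780313,54.8956734431035,99.6453885991055,118.608151716858,143.632848005903
21,North,Brancher,2014,2015,FALSE,24.9271786016601,36.0046221579253,0,0,0
22,North,Brancher,2014,2021,TRUE,7.23687218684221,6.31923955468453,5.33420441631212,8.54984093506085,10.8585168377167
23,North,Brancher,2014,2014,FALSE,43.2065757292295,0,0,0,0
24,North,Brancher,2014,2017,FALSE,3.01744823631445,2.80009507661194,2.1965663926334,0,0
25,North,Brancher,2014,2014,FALSE,317.705951111865,0,0,0,0
26,North,Brancher,2014,2014,FALSE,168.260555260351,0,0,0,0
27,North,Brancher,2014,2014,FALSE,58.3392705125231,0,0,0,0
28,North,Brancher,2014,2014,FALSE,364.154476856488,0,0,0,0
29,North,Brancher,2014,2021,TRUE,366.521840279936,391.539440245164,228.111025406464,195.184640031145,265.181984299126
30,North,Brancher,2014,2014,FALSE,237.298753135932,0,0,0,0
31,South,Encruster,2014,2021,TRUE,64.0625905957351,78.7764316409664,100.594062511608,131.610035389794,135.536200158572
32,South,Encruster,2014,2021,TRUE,17.8815221124998,20.3163361653208,26.0924551023034,42.9105585164046,66.5568819557979
33,South,Encruster,2014,2021,TRUE,73.874916898383,105.374419397822,58.1234156756499,43.0774668246146,49.3124274677333
34,South,Encruster,2014,2021,TRUE,124.34406181519,176.60135276459,148.894908381249,223.526724739606,265.068670115629
35,South,Encruster,2014,2021,TRUE,43.135037012316,56.4076386117548,72.3635734575893,69.4123384227668,104.852377059746
36,South,Encruster,2014,2021,TRUE,124.166758731951,103.756411260228,110.213872091332,155.54435520489,95.9654617973937
37,South,Encruster,2014,2021,TRUE,24.0419962386559,26.1602849430586,25.0645042078021,22.3089867725104,21.4197204676172
38,South,Encruster,2014,2021,TRUE,261.395402885289,336.027373720208,291.728827393803,370.534607661355,395.992496522885
39,South,Encruster,2014,2021,TRUE,26.2821718088159,14.8701878152794,16.8072312650443,28.1975634420689,25.1524664055372
40,South,Encruster,2014,2021,TRUE,1974.7316131492,1365.73271299223,1263.74356830493,982.589589728927,799.804162395657
41,South,Encruster,2014,2021,TRUE,7.23032633849913,7.10770090958264,9.99534161565896,10.9668658954647,12.1888814227894
42,South,Encruster,2014,2021,TRUE,304.607238571747,414.762764043076,640.703974766291,564.064523901671,560.367358864752
43,South,Encruster,2014,2021,TRUE,121.312083440533,106.478939670321,85.653317817591,98.7138759667696,96.970090700191
44,South,Encruster,2014,2021,TRUE,27.2089666930937,18.858767478189,19.1787877001667,31.3780651941828,48.7184527615428
45,South,Encruster,2014,2021,TRUE,127.33632846653,147.151778683721,130.740182505821,192.766280855896,152.105337713353
46,South,Brancher,2014,2014,FALSE,841.383527839228,0,0,0,0
47,South,Brancher,2014,2019,FALSE,141.847066952804,163.808074672876,165.756572786065,170.185280885143,0
48,South,Brancher,2014,2019,FALSE,43.8816443720544,79.6379550242062,97.7674030887986,105.788576175483,0
49,South,Brancher,2014,2015,FALSE,43.0782482118425,48.1362659332794,0,0,0
50,South,Brancher,2014,2014,FALSE,352.512115451803,0,0,0,0
51,South,Brancher,2014,2019,FALSE,277.057283490947,178.886938348812,253.670888889948,351.93520430085,0
52,South,Brancher,2014,2015,FALSE,83.8200879917953,84.1705376069348,0,0,0
53,South,Brancher,2014,2019,FALSE,93.7571052579358,111.006230360612,185.807737144777,154.085353925948,0
54,South,Brancher,2014,2015,FALSE,349.567491134835,637.247583650107,0,0,0
55,South,Brancher,2014,2014,FALSE,54.3015072529854,0,0,0,0
56,South,Brancher,2014,2014,FALSE,259.585221254756,0,0,0,0
57,South,Brancher,2014,2015,FALSE,50.587991864525,76.0474444877575,0,0,0
58,South,Brancher,2014,2015,FALSE,61.1069076264393,78.1409907587755,0,0,0
59,South,Brancher,2014,2015,FALSE,115.082305534514,114.166119416456,0,0,0
60,South,Brancher,2014,2014,FALSE,390.930916527556,0,0,0,0
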