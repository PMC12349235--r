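participant,digital_filters_db,anc_db,bayesian_ssp_db,ecg_db
1,16.2,31.0,34.4,35.3
2,13.1,28.8,37.0,43.8
3,12.5,28.5,43.3,40.3
4,8.2,26.6,38.9,53.3
5,13.1,20.8,29.9,28.5
6,13.3,25.8,34.6,32.4
7,16.4,34.1,41.3,39.3
8,9.9,22.8,36.1,40.2
9,12.9,23.5,28.5,32.7
10,12.1,26.2,32.9,26.5
11,5.7,25.9,42.7,54.0
12,11.1,22.5,35.1,28.6
13,13.5,25.4,36.2,37.9
14,12.6,26.6,30.2,35.1
15,10.0,26.9,28.5,31.8
16,12.4,27.3,44.3,41.7
17,3.6,21.6,23.3,32.9
18,6.0,26.6,35.4,42.5
19,7.5,28.1,37.6,42.0
20,2.4,18.7,30.9,29.1
21,13.3,19.4,31.2,35.8
22,5.7,20.5,27.2,46.3
23,12.2,26.7,36.8,40.7
24,5.7,18.3,28.4,40.8
25,13.8,32.8,36.1,34.3
26,10.9,31.0,39.0,31.5
27,7.0,27.1,38.3,42.9
28,11.8,33.5,35.5,36.6
29,4.3,29.8,41.8,31.6
30,8.1,24.6,31.2,37.6
31,9.5,20.4,28.1,37.9
32,7.2,23.7,32.1,26.5
33,2.8,27.1,38.8,41.2
34,6.6,27.5,37.6,46.6
35,4.2,11.1,22.0,34.2
36,11.4,28.0,41.4,39.4
37,12.0,22.4,36.8,43.0
38,13.2,32.1,37.7,38.3
39,13.1,29.8,38.4,48.0
40,7.0,33.7,36.8,35.7
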