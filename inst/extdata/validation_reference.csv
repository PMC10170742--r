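shark,initial_date,recapture_date,tal,ptal,abs_diff
1,18/11/2016,02/12/2016,14,18,4
2,20/11/2016,04/12/2016,14,9,5
3,01/12/2016,10/01/2017,9,10,1
4,22/12/2016,07/01/2017,16,8,8
5,06/12/2017,22/12/2017,16,14,2
6,06/12/2017,22/12/2017,16,13,3
7,17/01/2018,26/01/2018,9,13,4
8,13/11/2019,04/12/2019,21,10,11
9,04/12/2019,12/12/2019,8,14,6
10,04/12/2019,12/12/2019,8,12,4
11,06/10/2020,22/10/2020,16,19,3
12,06/10/2020,22/10/2020,16,7,9
13,05/10/2021,26/10/2021,21,12,9
14,11/10/2021,25/10/2021,14,15,1
15,12/11/2021,26/11/2021,14,22,8
16,30/11/2021,28/12/2021,28,25,3
17,06/12/2021,20/12/2021,14,16,2
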