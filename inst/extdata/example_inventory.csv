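tree_id,species,pft,a_bh,height,crown_base_height,a_cb,leaf_area,leaf_mass
1,sp05,EC,0.013924986987908207,7.18451700129294,2.716759961478454,0.010947245292026814,37.470635713805386,3.449772496679013
2,sp04,DB,0.011593899812009322,7.181202246745306,1.6572639063743058,0.01083729869151319,21.11454718983961,1.94370817723971
3,sp06,DC,0.024665781535581032,9.935159918728015,3.7366156637783874,0.015058833567846116,49.05222507413442,4.897251724513846
4,sp01,EC,0.03627137659443363,10.709053485928637,4.478196470271562,0.02140654646911435,47.16575189314219,4.798047399906037
5,sp06,DC,0.009656795302905022,8.09689040529853,4.8116338174740125,0.004831096952218572,18.98441530654453,1.800846894433349
6,sp01,EC,0.01401055537419353,8.008048305574942,3.9122150238763878,0.009197182796944568,39.222983515934835,3.710413372088983
7,sp04,DB,0.014034359689925554,8.754418339316336,6.018642138808985,0.005006945657729368,10.290538531614123,0.9953937904379967
8,sp05,EC,0.004716162798636219,6.3848922716985985,3.255613512429242,0.003052044059776268,8.038661370436225,0.7185750402127175
9,sp03,EB,0.006481091982830091,7.4042391246046595,3.57224784235917,0.004490667084769032,8.210939853594391,0.7616632120553639
10,sp05,EC,0.047891927044248495,10.952283462300057,5.366704287442832,0.027478477180027362,66.96043984635911,6.850061437299616
11,sp03,EB,0.009411380103438895,7.672290303951842,3.5197195469768907,0.006003065441107543,5.6428976235225905,0.5281209890704952
12,sp04,DB,0.0045031986348147,5.636006415333913,2.2453956743025993,0.0033828281707029588,3.8053548327841944,0.3297144863640951
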