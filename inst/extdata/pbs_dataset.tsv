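accession	organism	table	family	pbs_string	group	anomaly
NM_178014.2	Human (isotype I)	animal	isotype	EVDDHASFTSRRGL	C
NM_001069.2	Human (isotype IIa)	animal	isotype	EVDDHASFTSRRGL	C
NM_178012.4	Human (isotype IIb)	animal	isotype	EVDDHASFTSRRGL	C
NM_006088.5	Human (isotype IVb)	animal	isotype	EVDDHASFTSRRGL	C
NM_006086.3	Human (isotype III)	animal	isotype	EVDDHASFTARRGL	D
NM_006087.2	Human (isotype IVa)	animal	isotype	EVDDHASFTSRRGL	C
NM_032525.1	Human (isotype V)	animal	isotype	EVDDHASFTSRRGL	C
NM_030773.3	Human (isotype VI)	animal	isotype	EMEDHLSFTAQRGL	B
66734014	Ancylostoma duodenale	animal	animal	EVDDHVSFSAKRGL	D
159161	Haemonchus contortus	animal	animal	EVDDHVSFSAKRGL	D
62836546	Strongyloides stercoralis	animal	animal	EVEDHMSFAARKGL	D
3046907	Onchocerca volvulus	animal	animal	EVDDHVSFSARRGL	D
3046903	Dirofilaria immitis	animal	animal	EVDDHVSFSARRGL	D
156096	Brugia pahangi	animal	animal	EVDDHVSFSARRGL	D
19773428	Bombyx mori	animal	animal	EIDDHLSFTSRRGL	C
16974673	Saimiri sciureus	animal	animal	EVDDHASFSSRRGL	C
159727	Enteroctopus dofleini	animal	animal	EVEDHASFTSRTGL	C
289741319	Glossina morsitans	animal	animal	EVDDHASFTSRKGL	C
135490	Sus scrofa	animal	animal	EVDDHASFTSRRGL	C
50844501	Bos Taurus	animal	animal	EVDDHASFTSRRGL	C
10242164	Notothenia coriiceps	animal	animal	EVDDHASFTSRRGL	C
24645350	Drosophila melanogaster	animal	animal	EVDDHASFTSRRGL	C
1335661	Patella vulgata	animal	animal	EVDDHASFTSRRGL	C
56603670	Crassostrea gigas	animal	animal	EVDDHASFTSRRGL	C
51860821	Loligo pealei	animal	animal	EVDDHASFTSRRGL	C
74136187	Macaca mulatta	animal	animal	EVDDHASFTSRRGL	C
90960962	Pan troglodytes	animal	animal	EVDDHASFTSRRGL	C
49481	Cricetulus griseus	animal	animal	EVDDNASFTSRRGL	C
6892	Caenorhabditis elegans	animal	animal	EVDDHASFTSRRGL	C
10242186	Chionodraco rastrospinosus	animal	animal	EVDDHASFTSRRGL	C
4558495	Trichuris trichiura	animal	animal	EVDDHASFTSRRGL	C
16974663	Papio hamadryas	animal	animal	EVDDHASFTSRRGL	C
1769528	Heliothis virescens	animal	animal	EVDDHASFTSRRGL	C
30088884	Aplysia californica	animal	animal	EVDDHASFTSRRGL	C
17402390	Fasciola hepatica	animal	animal	EVDDHASFTSRRGL	C
135489	Paracentrotus lividus	animal	animal	EVDDHASFTSRRGL	C
7838279	Meriones unguiculatus	animal	animal	EVDDHASFTSRRGL	C
7838199	Echinococcus multilocularis	animal	animal	EVDDHASFTSRRGL	C
4455142	Lentinus sajor-caju	fungi	fungi	EVDDHISFTARRGC	D	duplicate
173523	Schizophyllum commune	fungi	fungi	EVDDHFSFTARRGL	D
74699315	Ustilago maydis	fungi	fungi	EVDDHLSFTARRGL	D
11229034	Melampsora lini	fungi	fungi	EVDDHISFTARRGL	D
55982602	Cochliobolus heterostrophus	fungi	fungi	EVDDHSSFTSRRGL	C
173523	Schizosaccharomyces pombe	fungi	fungi	STDDHAAFAAIKDL	B
3435	Saccharomyces cerevisiae	fungi	fungi	ETGDNSSYTAIQGL	B
170938	Candida albicans	fungi	fungi	ETGENSSYTSMKDL	B
77023508	Verticillium tricorpus	fungi	fungi	QNGDHASFTSRRGL	A
299296	Phaeosphaeria nodorum	fungi	fungi	QTGDHASFTSRRGL	A
58119500	Phaeosphaeria avenaria	fungi	fungi	QTGDHASFTSRRGL	A
170600	Venturia inaequalis	fungi	fungi	QTGDHASFTSRRGL	A
61678005	Cercospora beticola	fungi	fungi	QTGDHASFTSRRGL	A
30961893	Monilinia fructicola	fungi	fungi	QTGDHASFTSRRGL	A
166496	Aspergillus flavus	fungi	fungi	QTGDHASFTSRRGL	A
168105	Emericella nidulans	fungi	fungi	QTGDHASFTSRRGL	A
639766	Ajellomyces capsulatus	fungi	fungi	QTGDHASFTSRRGL	A
2852439	Mycosphaerella pini	fungi	fungi	QTGDHASFTSRRGL	A
1002511	Botryotinia fuckeliana	fungi	fungi	QTGDHASFTSRRGL	A
602578	Erysiphe pisi	fungi	fungi	QTGDHASFTSRRGL	A
1060942	Penicillium digitatum	fungi	fungi	QTGDHASFTSRRGL	A
6652864	Pestalotiopsis microspora	fungi	fungi	QTGDHASFTSRRGL	A
1263904	Rhynchosporium secalis	fungi	fungi	QTGDHASFTSRRGL	A
2718	Epichloe typhina	fungi	fungi	QTGDYASFTSRRGL	A
849160	Gibberella fujikuroi	fungi	fungi	QTGDYASFTSRRGL	A
2293	Neotyphodium coenophialum	fungi	fungi	QTGDYASFTSRRDL	A
32130590	Gibberella zeae	fungi	fungi	QTGDYASFTSRRGL	A
167300	Glomerella graminicola	fungi	fungi	QTGHHRSFTS-KGL	A
169400	Pneumocystis carinii	fungi	fungi	STGDHASFTSKRGL	A
4455142	Lentinus sajor-caju	plant	plant	EVDDHISFTARRGC	C	duplicate
1488052	Daucus carota	plant	plant	EVDDHGSFTSRRGL	C
460991	Oryza sativa	plant	plant	EVDDHASFTSRRGL	C
4415996	Eleusine indica	plant	plant	EVDDHASFTSRRGL	C
224106013	Populus trichocarpa	plant	plant	EVDDHASFTSRRGL	C
1403143	Cicer arietinum	plant	plant	EVDDHASFTSRKNL	C
244539475	Lotus japonicus	plant	plant	EVDDHASFTSRKGL	C
153799899	Eucalyptus grandis	plant	plant	EVDDHASFTSRKGL	C
255564502	Ricinus communis	plant	plant	EVDDHASFTSRKGL	C
312989	Glycine max	plant	plant	EVDDHASFTSRKGL	C
223018283	Citrus maxima	plant	plant	EVDDHASFTSRKGL	C
295851	Zea mays	plant	plant	EVADHASFTSRHGL	C
609270	Solanu tuberosum	plant	plant	EVDDHASFTSRTGL	C
77963735	Solanum lycopersicum	plant	plant	EVDDHASFTSRTGL	C
40036995	Nicotiana attenuata	plant	plant	EVDDHASFTSRTGL	C
1743277	Hordeum vulgare	plant	plant	EVDDHASFTSRTGL	C
14331109	Medicago sativa	plant	plant	EVDDHTSFTSRTGL	C
145388977	Capsicum annuum	plant	plant	EVDDHASFTSRTGL	C
37038246	Physcomitrella patens	plant	plant	EVEDHASFTSRTGL	C
402636	Lupinus albus	plant	plant	EVADHASFTSRTGL	C
20758	Pisum sativum	plant	plant	EVADHASFTSRTGL	C
20148289	Arabidopsis thaliana	plant	plant	EVADHASFTSRTGL	C
51988178	Setaria viridis	plant	plant	EVADHASFTSRTGL	C
205326619	Prunus salicina	plant	plant	EVADHASFTSRTGL	C
5668669	Zinnia elegans	plant	plant	EVTDHASFTSRTGL	C
296498	Anemia phyllitidis	plant	plant	EVTDHASFTSRVGL	C
4098333	Triticum aestivum	plant	plant	EVGDHASFTSRVGL	C
19569609	Gossypium hirsutum	plant	plant	EVADHASFTSRIGL	C
155874	Babesia bovis	protist	protist	EVDDHASFTSRKGL	C
29420520	Babesia microti	protist	protist	EVDDHASFTSRKGL	C
295762	Plasmodium falciparum	protist	protist	EVDDHASFTSRKGL	C
4079637	Tetrahymena pyriformis	protist	protist	EVDDHASFTSRKGL	C
161737	Tetrahymena thermophila	protist	protist	EVDDHASFTSRKGL	C
6007456	Stylonychia mytilus	protist	protist	EVDDHASFTSRKGL	C
9309	Euplotes octocarinatus	protist	protist	EVDDHASFTSRKGL	C
2155306	Chlamydomonas incerta	protist	protist	EVDDHASFTSRKGL	C
167456	Chlamydomonas reinhardtii	protist	protist	EVDDHASFTSRKGL	C
166302	Achlya klebsiana	protist	protist	EVDDHASFTSRKGL	C
68128910	Leishmania major	protist	protist	EVDDHASFTSRKGL	C
6652866	Pythium ultimum	protist	protist	EVDDHASFTSRKGL	C
639490	Eimeria tenella	protist	protist	EVDDHASFTSRKGL	C
161939	Toxoplasma gondii	protist	protist	EVDDHASFTSRKGL	C
23481527	Plasmodium yoelii yoelii	protist	protist	EVDDHASFTSRKGL	C
290685	Moneuplotes crassus	protist	protist	EVDDHASFTSRKGL	C
38520885	Paramecium tetraurelia	protist	protist	EVDDHASFTSRKGL	C
295443942	Palpitomonas bilix	protist	protist	EVDDHASFTSRKGL	C
238617571	Leucocryptos marina	protist	protist	EVDDHASFTSRKGL	C
302849658	Volvox carteri	protist	protist	EVDDHASFTSRKGL	C
135500	Trypanosoma brucei rhodesiens	protist	protist	EVDDHASFTSRKGL	C
206598211	Bodo saltans	protist	protist	EVDDHASFTSRKGL	C
159416	Leishmania mexicana	protist	protist	EVDDHASFTSRKGL	C
135494	Polytomella agilis	protist	protist	EVDDHASFTSRKGL	C
829213	Naegleria gruberi	protist	protist	EVDDHISFTSRRGL	C
8926601	Thalassiosira weissflogii	protist	protist	EVDDHACYTSRKGL	C
2951981	Phytophthora cinnamomi	protist	protist	EVDDHASFTSRQGL	C
29150706	Porphyra yezoensis	protist	protist	EVEDKGSYSADTGE	D
29539330	Cyanidioschyzon merolae	protist	protist	EVEDKGSLTATKGL	D
1067176	Porphyra purpurea	protist	protist	EVEDKGSYSADTGE	D
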