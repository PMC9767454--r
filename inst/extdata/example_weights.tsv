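snp_id	chrom	pos	effect_allele	other_allele	beta	se	p_value
rs000001	1	1	A	C	-0.13670541500232333	0.004003925449596091	1.7074299457342328e-255
rs000002	1	1000001	A	G	-0.1831418754475977	0.004792310756900352	1e-300
rs000003	1	2000001	T	C	0.037825310710454585	0.00418632748812582	1.6334400866386406e-19
rs000004	1	3000001	T	G	-0.1969555252873778	0.003930466488815886	1e-300
rs000005	1	4000001	C	A	-0.009057267054876623	0.004692008297965338	0.053562196918382564
rs000006	1	5000001	G	A	0.050719358604715846	0.003974542303037672	2.7050736883338614e-37
rs000007	1	6000001	C	T	0.042702498041341415	0.004498499621194506	2.2532279678022574e-21
rs000008	1	7000001	G	T	0.18746665026949744	0.005032441540648914	1e-300
rs000009	1	8000001	A	C	6.218462818475924e-4	0.004001607394077336	0.8765066750749051
rs000010	1	9000001	A	G	-0.10987476719743978	0.006556701266011187	4.980953726881454e-63
rs000011	1	10000001	T	C	-0.12122883901079232	0.003741154092667535	2.400706434726529e-230
rs000012	1	11000001	T	G	-0.2372685138311211	0.0040468173387472745	1e-300
rs000013	1	12000001	C	A	0.022968758335027657	0.0043180320085453765	1.0418705100627358e-7
rs000014	1	13000001	G	A	0.016287781425031008	0.004544907753340477	3.387053378748359e-4
rs000015	1	14000001	C	T	-0.0883345237108889	0.00459472904941276	2.2781782964412926e-82
rs000016	1	15000001	G	T	-0.04445430206487402	0.00399845872260919	1.0270662770231623e-28
rs000017	1	16000001	A	C	-0.019315437458544023	0.006245054429868089	0.0019819929819385727
rs000018	1	17000001	A	G	-0.09908129467205717	0.00401395217878402	1.5798900018657856e-134
rs000019	1	18000001	T	C	-0.10992318427797473	0.0060414865924093624	5.682409291098547e-74
rs000020	1	19000001	T	G	0.0740431640269303	0.0058979872111879095	3.780611708689269e-36
rs000021	1	20000001	C	A	0.2696420304575531	0.008062541075503324	3.1671712912810457e-245
rs000022	1	21000001	G	A	2.8129070267217393e-5	0.006925200180115281	0.996759127739641
rs000023	1	22000001	C	T	-0.03800182096016354	0.004090636709924783	1.543571151751867e-20
rs000024	1	23000001	G	T	0.05541946487338065	0.003825741345224271	1.4867172887938555e-47
rs000025	1	24000001	A	C	-0.19663108609527383	0.0040983556794797135	1e-300
rs000026	1	25000001	A	G	0.15293083385738457	0.004875655623340399	5.849209740136214e-216
rs000027	1	26000001	T	C	-0.0343779544743637	0.004399840972477344	5.564178441600557e-15
rs000028	1	27000001	T	G	-0.02351452916378749	0.004068617674421409	7.492806406970339e-9
rs000029	1	28000001	C	A	0.09132567814957912	0.008814943552459497	3.7568419655786414e-25
rs000030	1	29000001	G	A	-0.013546616001921233	0.009247066656958939	0.14293085074702042
rs000031	1	30000001	C	T	-0.11819093784203527	0.004745274943764097	6.235862901052032e-137
rs000032	1	31000001	G	T	-0.10722009364116025	0.005506997392310182	1.980742327994816e-84
rs000033	1	32000001	A	C	-0.022693836397258076	0.006038831577298763	1.712873831733094e-4
rs000034	1	33000001	A	G	-0.018030103394937255	0.00385583283601954	2.9243992552987763e-6
rs000035	1	34000001	T	C	0.08553962091397696	0.00413286006404266	3.6526823685552705e-95
rs000036	1	35000001	T	G	0.26143780929914945	0.004223651498603934	1e-300
rs000037	1	36000001	C	A	0.336063926848417	0.008686457589520911	1e-300
rs000038	1	37000001	G	A	-0.2113718139842065	0.003877131292784256	1e-300
rs000039	1	38000001	C	T	-0.18587092202112532	0.009329936705586857	2.623452326635299e-88
rs000040	1	39000001	G	T	-0.13079593264006442	0.004689935489815955	3.664081148661416e-171
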