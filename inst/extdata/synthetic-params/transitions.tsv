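sex	age_lo	age_hi	from	to	value	ci_lower	ci_upper
male	45	50	no_lesion	nonadv_adenoma	0.011531610351479612	0.0098018687987576694	0.013261351904201553
male	50	55	no_lesion	nonadv_adenoma	0.01381692182960687	0.011744383555165839	0.0158894601040479
male	55	60	no_lesion	nonadv_adenoma	0.015036337609936015	0.012780886968445612	0.017291788251426417
male	60	65	no_lesion	nonadv_adenoma	0.017088680801563894	0.014525378681329309	0.019651982921798476
male	65	70	no_lesion	nonadv_adenoma	0.018469310000848487	0.015698913500721213	0.021239706500975758
male	70	75	no_lesion	nonadv_adenoma	0.021959021139333491	0.018665167968433469	0.025252874310233514
male	75	80	no_lesion	nonadv_adenoma	0.024027313838100525	0.020423216762385444	0.027631410913815602
male	45	50	nonadv_adenoma	adv_adenoma	0.011763825707221402	0.0099992518511381918	0.013528399563304611
male	50	55	nonadv_adenoma	adv_adenoma	0.013939899491646793	0.011848914567899774	0.016030884415393812
male	55	60	nonadv_adenoma	adv_adenoma	0.014844659813104663	0.012617960841138963	0.017071358785070361
male	60	65	nonadv_adenoma	adv_adenoma	0.016413906848430634	0.013951820821166038	0.018875992875695226
male	65	70	nonadv_adenoma	adv_adenoma	0.018498075991561634	0.015723364592827388	0.021272787390295877
male	70	75	nonadv_adenoma	adv_adenoma	0.018693934731581249	0.015889844521844061	0.021498024941318434
male	75	80	nonadv_adenoma	adv_adenoma	0.020723303457638249	0.017614807938992512	0.023831798976283985
male	45	50	adv_adenoma	preclin_crc	0.020947473534126765	0.017805352504007749	0.024089594564245777
male	50	55	adv_adenoma	preclin_crc	0.022921385490824467	0.019483177667200795	0.026359593314448135
male	55	60	adv_adenoma	preclin_crc	0.026024986868142152	0.022121238837920828	0.029928734898363472
male	60	65	adv_adenoma	preclin_crc	0.027408891313383355	0.02329755761637585	0.031520225010390854
male	65	70	adv_adenoma	preclin_crc	0.02829774259706028	0.024053081207501239	0.032542403986619318
male	70	75	adv_adenoma	preclin_crc	0.031290006031026128	0.026596505126372207	0.035983506935680046
male	75	80	adv_adenoma	preclin_crc	0.031476054617995401	0.02675464642529609	0.036197462810694706
male	45	50	preclin_crc	clin_crc	0.2187366814147681	0.18592617920255289	0.25154718362698331
male	50	55	preclin_crc	clin_crc	0.21926945352973415	0.18637903550027402	0.25215987155919423
male	55	60	preclin_crc	clin_crc	0.22582831406267359	0.19195406695327255	0.25970256117207463
male	60	65	preclin_crc	clin_crc	0.22582831406267359	0.19195406695327255	0.25970256117207463
male	65	70	preclin_crc	clin_crc	0.22582831406267359	0.19195406695327255	0.25970256117207463
male	70	75	preclin_crc	clin_crc	0.22582831406267359	0.19195406695327255	0.25970256117207463
male	75	80	preclin_crc	clin_crc	0.22582831406267359	0.19195406695327255	0.25970256117207463
female	45	50	no_lesion	nonadv_adenoma	0.0083037556266333887	0.0070581922826383802	0.0095493189706283964
female	50	55	no_lesion	nonadv_adenoma	0.0099122980443773785	0.0084254533377207709	0.011399142751033984
female	55	60	no_lesion	nonadv_adenoma	0.010942802258417754	0.0093013819196550909	0.012584222597180415
female	60	65	no_lesion	nonadv_adenoma	0.012690316570946016	0.010786769085304114	0.014593864056587918
female	65	70	no_lesion	nonadv_adenoma	0.014442861303037405	0.012276432107581794	0.016609290498493016
female	70	75	no_lesion	nonadv_adenoma	0.015019949263755978	0.012766956874192581	0.017272941653319374
female	75	80	no_lesion	nonadv_adenoma	0.016545714479560776	0.014063857307626659	0.019027571651494889
female	45	50	nonadv_adenoma	adv_adenoma	0.0088499569282567119	0.0075224633890182049	0.010177450467495217
female	50	55	nonadv_adenoma	adv_adenoma	0.010025797369026391	0.0085219277636724312	0.011529666974380348
female	55	60	nonadv_adenoma	adv_adenoma	0.010622390749722719	0.0090290321372643104	0.012215749362181125
female	60	65	nonadv_adenoma	adv_adenoma	0.011531370366593822	0.0098016648116047485	0.013261075921582894
female	65	70	nonadv_adenoma	adv_adenoma	0.013398152074298635	0.011388429263153839	0.015407874885443429
female	70	75	nonadv_adenoma	adv_adenoma	0.013398152074298635	0.011388429263153839	0.015407874885443429
female	75	80	nonadv_adenoma	adv_adenoma	0.015561864160950111	0.013227584536807594	0.017896143785092626
female	45	50	adv_adenoma	preclin_crc	0.015438811686560512	0.013122989933576435	0.017754633439544587
female	50	55	adv_adenoma	preclin_crc	0.016468644828261807	0.013998348104022536	0.018938941552501077
female	55	60	adv_adenoma	preclin_crc	0.017740895513724535	0.015079761186665853	0.020402029840783212
female	60	65	adv_adenoma	preclin_crc	0.01944873926853016	0.016531428378250636	0.022366050158809683
female	65	70	adv_adenoma	preclin_crc	0.020143921103775501	0.017122332938209174	0.023165509269341824
female	70	75	adv_adenoma	preclin_crc	0.021318386682936924	0.018120628680496385	0.02451614468537746
female	75	80	adv_adenoma	preclin_crc	0.023777231565305961	0.020210646830510066	0.027343816300101853
female	45	50	preclin_crc	clin_crc	0.21549745421344416	0.18317283608142754	0.24782207234546075
female	50	55	preclin_crc	clin_crc	0.2268437263239175	0.19281716737532986	0.26087028527250511
female	55	60	preclin_crc	clin_crc	0.23036047145491467	0.19580640073667746	0.26491454217315186
female	60	65	preclin_crc	clin_crc	0.23036047145491467	0.19580640073667746	0.26491454217315186
female	65	70	preclin_crc	clin_crc	0.23036047145491467	0.19580640073667746	0.26491454217315186
female	70	75	preclin_crc	clin_crc	0.23036047145491467	0.19580640073667746	0.26491454217315186
female	75	80	preclin_crc	clin_crc	0.23036047145491467	0.19580640073667746	0.26491454217315186
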