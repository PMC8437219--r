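sex	age_lo	age_hi	state	value	ci_lower	ci_upper
male	45	50	nonadv_adenoma	0.16085158152482476	0.13672384429610104	0.18497931875354845
male	50	55	nonadv_adenoma	0.18996786435984539	0.16147268470586856	0.21846304401382219
male	55	60	nonadv_adenoma	0.21024770747451116	0.17871055135333447	0.24178486359568782
male	60	65	nonadv_adenoma	0.24571451046899895	0.20885733389864911	0.28257168703934876
male	65	70	nonadv_adenoma	0.28772994335740809	0.24457045185379686	0.33088943486101929
male	70	75	nonadv_adenoma	0.31965081484208357	0.27170319261577103	0.36759843706839607
male	75	80	nonadv_adenoma	0.32130964170955123	0.27311319545311852	0.36950608796598389
male	45	50	adv_adenoma	0.024883948643878103	0.021151356347296386	0.028616540940459817
male	50	55	adv_adenoma	0.033413819437427453	0.028401746521813334	0.038425892353041564
male	55	60	adv_adenoma	0.041454313077405103	0.035236166115794339	0.047672460039015867
male	60	65	adv_adenoma	0.051077637786511337	0.043415992118534634	0.058739283454488034
male	65	70	adv_adenoma	0.059495218853931886	0.050570936025842103	0.068419501682021669
male	70	75	adv_adenoma	0.062712724394397817	0.053305815735238141	0.07211963305355748
male	75	80	adv_adenoma	0.075796735467808324	0.064427225147637074	0.08716624578797956
male	45	50	preclin_crc	0.0014538627821020782	0.0012357833647867664	0.0016719421994173898
male	50	55	preclin_crc	0.0024880249068373814	0.0021148211708117742	0.0028612286428629885
male	55	60	preclin_crc	0.0034377515479107391	0.0029220888157241282	0.0039534142800973495
male	60	65	preclin_crc	0.0043240821333602074	0.003675469813356176	0.0049726944533642382
male	65	70	preclin_crc	0.0053840942990034824	0.0045764801541529603	0.0061917084438540045
male	70	75	preclin_crc	0.0067076467156177398	0.0057014997082750788	0.0077137937229603999
male	75	80	preclin_crc	0.0074939757751417355	0.006369879408870475	0.0086180721414129951
female	45	50	nonadv_adenoma	0.11336233653559349	0.096357986055254474	0.13036668701593251
female	50	55	nonadv_adenoma	0.127479085175246	0.1083572223989591	0.14660094795153289
female	55	60	nonadv_adenoma	0.15455910624844951	0.13137524031118208	0.17774297218571691
female	60	65	nonadv_adenoma	0.17244042547739111	0.14657436165578244	0.19830648929899974
female	65	70	nonadv_adenoma	0.20696698870081454	0.17592194039569234	0.23801203700593671
female	70	75	nonadv_adenoma	0.21138153130198831	0.17967430160669007	0.24308876099728655
female	75	80	nonadv_adenoma	0.24145527617999354	0.20523698475299451	0.27767356760699258
female	45	50	adv_adenoma	0.017796483612701294	0.015127011070796099	0.020465956154606488
female	50	55	adv_adenoma	0.024383046035941689	0.020725589130550434	0.028040502941332941
female	55	60	adv_adenoma	0.029543784658525141	0.025112216959746369	0.033975352357303909
female	60	65	adv_adenoma	0.034280110095720739	0.029138093581362629	0.03942212661007885
female	65	70	adv_adenoma	0.041402419438596814	0.03519205652280729	0.047612782354386332
female	70	75	adv_adenoma	0.045656277006536718	0.03880783545555621	0.052504718557517219
female	75	80	adv_adenoma	0.055646159603264175	0.047299235662774546	0.063993083543753798
female	45	50	preclin_crc	0.0010312215786483136	0.00087653834185106661	0.0011859048154455607
female	50	55	preclin_crc	0.0018792293384531514	0.0015973449376851787	0.0021611137392211241
female	55	60	preclin_crc	0.0024039887630520388	0.0020433904485942329	0.0027645870775098442
female	60	65	preclin_crc	0.0033586379225850104	0.0028548422341972586	0.0038624336109727617
female	65	70	preclin_crc	0.003995559793886729	0.0033962258248037194	0.0045948937629697378
female	70	75	preclin_crc	0.0045097631245991218	0.0038332986559092533	0.0051862275932889898
female	75	80	preclin_crc	0.0054395985090639441	0.0046236587327043522	0.0062555382854235352
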