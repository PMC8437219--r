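sex	age	value
male	45	32.683725106182557
male	46	32.124915024385686
male	47	31.539080175072215
male	48	30.926845630302772
male	49	30.289143861628663
male	50	29.627227686575214
male	51	28.94267452437942
male	52	28.237380076610233
male	53	27.513539817836985
male	54	26.773617184129673
male	55	26.020298108737325
male	56	25.256432572949713
male	57	24.484965072772336
male	58	23.708857252126162
male	59	22.931007264492671
male	60	22.154171485771673
male	61	21.380894766390831
male	62	20.609539177742018
male	63	19.846072214582577
male	64	19.093145449124343
male	65	18.352071540435912
male	66	17.623619473819733
male	67	16.908333910321222
male	68	16.206662753628898
male	69	15.519007352623426
male	70	14.845741452129383
male	71	14.187217493330735
male	72	13.543767777897536
male	73	12.915703538203299
male	74	12.303313150650254
male	75	11.706859998615052
male	76	11.126580193992725
male	77	10.562680242419578
male	78	10.015334681782049
male	79	9.4846836933278418
male	80	8.970830661035599
male	81	8.4738396287683777
male	82	7.9937325700227921
male	83	7.5304863355569109
male	84	7.0840290713978478
male	85	6.6542357908166272
male	86	6.240922618215885
male	87	5.843838966723621
male	88	5.4626565081162157
male	89	5.0969531471537532
male	90	4.7461891548941892
male	91	4.4096708492435255
male	92	4.086494194521693
male	93	3.7754554166472802
male	94	3.4749062675540294
male	95	3.1825141246421587
male	96	2.894853969566793
male	97	2.6066942674085944
male	98	2.3097065922569264
male	99	1.9900495035184111
male	100	1.6236608755668793
female	45	34.906430108611076
female	46	34.454474294140233
female	47	33.973917216318185
female	48	33.46429729508349
female	49	32.925385322304436
female	50	32.357219884380314
female	51	31.760140930720262
female	52	31.134819529228245
female	53	30.482281533497332
female	54	29.803922655008304
female	55	29.101512347707029
female	56	28.377184041021682
female	57	27.633409671342232
female	58	26.872957221607628
female	59	26.098831117126725
female	60	25.314196827971582
female	61	24.522292808267402
female	62	23.709378011189024
female	63	22.894070116320048
female	64	22.0841172497597
female	65	21.282900967818144
female	66	20.492048178291331
female	67	19.712479974094528
female	68	18.94483223868259
female	69	18.189623582116926
female	70	17.447321542277237
female	71	16.718367737850091
female	72	16.003186384957054
female	73	15.302186001380973
female	74	14.61575825169815
female	75	13.944275520906247
female	76	13.288087847360922
female	77	12.647519454335058
female	78	12.022864952957464
female	79	11.414385209491824
female	80	10.822302819581738
female	81	10.246797085757835
female	82	9.68799833844764
female	83	9.1459813642475112
female	84	8.6207575961907335
female	85	8.1122655623283997
female	86	7.6203588557308857
female	87	7.1447905413987405
female	88	6.6851923904594255
female	89	6.2410465272023421
female	90	5.8116458214423838
female	91	5.3960373744807413
female	92	4.9929402473950022
female	93	4.6006233198931659
female	94	4.2167203367619575
female	95	3.8379440374758449
female	96	3.459634599342285
female	97	3.0750294874408794
female	98	2.6740524105174943
female	99	2.2412478739791024
female	100	1.7521486848252759
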