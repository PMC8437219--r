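sex	age	value
male	45	0.0025761456843325656
male	46	0.0028131204879053638
male	47	0.0030718941586268247
male	48	0.0033544719333482961
male	49	0.0036630435068933024
male	50	0.0040000000000000001
male	51	0.0043679524881127902
male	52	0.0047697522346026779
male	53	0.0052085127852035768
male	54	0.0056876340948743094
male	55	0.0062108288740453437
male	56	0.0067821513584072797
male	57	0.007406028725178153
male	58	0.0080872953992941771
male	59	0.0088312305153625294
male	60	0.0096435988256688386
male	61	0.010530695371235447
male	62	0.011499394262086429
male	63	0.012557201944717586
male	64	0.013712315369540987
male	65	0.014973685509043447
male	66	0.01635108671886119
male	67	0.017855192479249431
male	68	0.019497658103867582
male	69	0.02129121105679023
male	70	0.023249749577610349
male	71	0.025388450378880607
male	72	0.027723886250439912
male	73	0.030274154481941245
male	74	0.033059017098726565
male	75	0.036100053997736477
male	76	0.039420830170104781
male	77	0.043047078306245226
male	78	0.047006898198437494
male	79	0.051330974486082419
male	80	0.056052814430934433
male	81	0.06120900756483115
male	82	0.066839509221929702
male	83	0.072987950152541406
male	84	0.079701974617761379
male	85	0.087033609584788285
male	86	0.095039667883828283
male	87	0.10378218845064525
male	88	0.11332891706619659
male	89	0.12375383131860539
male	90	0.13513771385539816
male	91	0.14756877836814017
male	92	0.16114335316022069
male	93	0.17596662759475601
male	94	0.1921534672068328
male	95	0.20982930379639622
male	96	0.22913110739911083
male	97	0.25020844766699629
male	98	0.27322465288347381
male	99	0.29835807559403044
male	100	0.32580347465987231
female	45	0.0015782091137673149
female	46	0.0017302929542218259
female	47	0.0018970323269031034
female	48	0.0020798395095666796
female	49	0.002280262873862726
female	50	0.0025000000000000001
female	51	0.002740912055202042
female	52	0.0030050395577407535
female	53	0.0032946196600682582
female	54	0.0036121050974346975
female	55	0.0039601849624862047
female	56	0.0043418074818033147
female	57	0.0047602049872964508
female	58	0.0052189212939654905
female	59	0.0057218417159122627
female	60	0.006273225974840744
female	61	0.0068777442797790323
female	62	0.0075405168836172962
female	63	0.0082671574515044716
female	64	0.0090638206084328009
female	65	0.0099372540687368699
female	66	0.010894855789042573
female	67	0.011944736628749822
female	68	0.013095789048781512
female	69	0.014357762430475256
female	70	0.01574134565256664
female	71	0.017258257625688868
female	72	0.018921346551213278
female	73	0.020744698745150426
female	74	0.022743757948847001
female	75	0.024935456137036797
female	76	0.027338356931186369
female	77	0.029972812832842012
female	78	0.032861137608740466
female	79	0.036027795287779989
female	80	0.039499607370650988
female	81	0.043305980007185899
female	82	0.047479153065613788
female	83	0.052054473203329545
female	84	0.057070693252079051
female	85	0.06257030045334451
female	86	0.068599876324074313
female	87	0.07521049120080979
female	88	0.082458136803986698
female	89	0.090404200486218542
female	90	0.099115985181431457
female	91	0.108667279458805
female	92	0.11913898250985919
female	93	0.13061978936231133
female	94	0.14320694212444426
female	95	0.15700705362300413
female	96	0.1721370104108183
female	97	0.18872496279258047
female	98	0.20691141025429641
female	99	0.22685039148994254
female	100	0.24871078910483443
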