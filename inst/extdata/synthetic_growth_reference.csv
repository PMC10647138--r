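"sex","age","thin3","thin2","thin1","overweight","obesity","morbid_obesity"
"female",6,12.4213170662076,12.9950739526906,13.7771915633591,17.4057410692438,19.7599043498287,21.8635716599785
"female",7,12.7391639760481,13.3654016852273,14.2422695751972,18.0191658038183,20.5652509404958,23.0268757728719
"female",8,12.9742073317838,13.7333517236325,14.6306242974514,18.6912606824758,21.471841672727,24.1152159879449
"female",9,13.2293703895771,13.9684992292882,14.8948631192551,19.254454968178,22.2072316661388,25.1631682936572
"female",10,13.539520584239,14.3292681052869,15.3068541011374,19.9883643634686,23.1198353738009,26.2803420448081
"female",11,13.8961426012247,14.7296796373593,15.6912860939692,20.498792763482,24.0013641119271,27.2760693490011
"female",12,14.1584309628199,14.9501346035279,16.0905628565726,21.1297943348512,24.8002094165634,28.3735084758865
"female",13,14.435368793561,15.3611311079252,16.479323112906,21.7566471734978,25.6162404629393,29.4917791486859
"female",14,14.748855113127,15.61630162476,16.8394586427289,22.3712864863877,26.4700080220217,30.5004719423537
"female",15,15.0709748096316,15.8664677959107,17.2723591430395,22.9325525088231,27.2977011936582,31.5772735047778
"female",16,15.3036619276326,16.2637468277743,17.5448028620493,23.6900791656009,28.0752513781894,32.6542818132597
"female",17,15.5723373280812,16.5532548832737,18.1283687439481,24.2539947809847,28.9399349734783,33.6691988899457
"female",18,15.9425093550636,16.9140720083643,18.3915965812728,24.8285318926273,29.7756269844929,34.7712403851692
"male",6,12.4486773094629,13.0991821662111,13.8332185693795,17.5797640401069,19.8164753885908,22.0089765807941
"male",7,12.7977047859548,13.4527495685898,14.2892057342493,18.1097305806422,20.7255890584225,23.1486588284872
"male",8,13.0356046376396,13.6309316723078,14.7020798792405,18.7477533195492,21.4991904868451,24.2555251438676
"male",9,13.4010610597549,14.0971950660609,15.0771988685804,19.4141068150366,22.3537282491683,25.1880324152068
"male",10,13.6843246207281,14.3905268963569,15.4088768913314,19.926462380805,23.1760924972446,26.3875637446767
"male",11,14.0146006442431,14.7140272802995,15.8214669139113,20.6223097479709,23.9811470221586,27.4250836051683
"male",12,14.2202855023145,15.0420343301644,16.2425012685992,21.2881587874229,24.8917738201873,28.5123319159932
"male",13,14.5681815021036,15.398666493267,16.5384788819392,21.8396252421519,25.7682290981068,29.6425933128924
"male",14,14.8210493560592,15.7407220529894,16.9782386273517,22.4693986803375,26.6170559845712,30.6268651785293
"male",15,15.1916511850851,16.1215199949253,17.3253889261767,23.0727932686842,27.4784859813721,31.755747269806
"male",16,15.5334142213586,16.3463713331967,17.7636536347892,23.751400107939,28.2628363395559,32.8511062816424
"male",17,15.6164187352221,16.7474444097448,18.1222460002439,24.4836305835181,29.173775476445,33.8853360117872
"male",18,16.0305363176745,16.9532951184178,18.437318329988,25.0145723117759,29.9778354063391,35.0000552675816
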