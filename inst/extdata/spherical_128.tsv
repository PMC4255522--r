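channel_id	x	y	z
E001	0.0391707271825257	-0.100747565015744	0.994140625
E002	-0.167406222125958	0.0825979195561173	0.982421875
E003	0.230705471263745	0.0671597248669737	0.970703125
E004	-0.147165832469761	-0.242262639008456	0.958984375
E005	-0.0623249191768154	0.314330145138774	0.947265625
E006	0.284682558919829	-0.209064309064441	0.935546875
E007	-0.380568799018388	-0.0413398678358612	0.923828125
E008	0.270609897116004	0.30793955838764	0.912109375
E009	0.00899024964999214	-0.434989537602159	0.900390625
E010	-0.316662264080869	0.331643346218739	0.888671875
E011	0.479501764986578	-0.0321134539950294	0.876953125
E012	-0.39149737749279	-0.313208045450029	0.865234375
E013	0.0801387392428864	0.514867808620252	0.853515625
E014	0.299072154362146	-0.449370523872471	0.841796875
E015	-0.54140462547188	0.133608899082876	0.830078125
E016	0.504440339499807	0.275368620643183	0.818359375
E017	-0.191235189199063	-0.559249501127724	0.806640625
E018	-0.243033577816637	0.555908169305083	0.794921875
E019	0.568479936594077	-0.251840081560162	0.783203125
E020	-0.603020964665286	-0.202922584511946	0.771484375
E021	0.31431980583708	0.569174186630859	0.759765625
E022	0.155860525468838	-0.645084001819385	0.748046875
E023	-0.561444074194746	0.377626063567637	0.736328125
E024	0.681469432271141	0.102667748305681	0.724609375
E025	-0.440757935406681	-0.545453388625599	0.712890625
E026	-0.0441732118556459	0.711622602973894	0.701171875
E027	0.521428080083739	-0.502759530718136	0.689453125
E028	-0.735066955973455	0.0187799674994027	0.677734375
E029	0.562720981390421	0.489661397660527	0.666015625
E030	-0.0853336665901015	-0.751407855103687	0.654296875
E031	-0.450515678793909	0.619781394067576	0.642578125
E032	0.760335487644747	-0.154616930517435	0.630859375
E033	-0.673132909778004	-0.404421775190711	0.619140625
E034	0.225750149596302	0.761626900607333	0.607421875
E035	0.351876718406303	-0.722025319437515	0.595703125
E036	-0.755147193250555	0.29785057710481	0.583984375
E037	0.765770860349854	0.293440017520452	0.572265625
E038	-0.370038736544667	-0.740849873040524	0.560546875
E039	-0.22972886121101	0.803748928170779	0.548828125
E040	0.718776379377154	-0.441445393833233	0.537109375
E041	-0.835410509761974	-0.161412426229667	0.525390625
E042	0.51121884931872	0.68905478224538	0.513671875
E043	0.0892054523245873	-0.860282190666702	0.501953125
E044	-0.65189766859021	0.578532356273189	0.490234375
E045	0.87796962547715	0.0138612182138533	0.478515625
E046	-0.642591507645236	-0.607599236168428	0.466796875
E047	0.0638359624447108	0.888160385316324	0.455078125
E048	0.556531622090912	-0.702641457795132	0.443359375
E049	-0.890626117124618	0.143078615960372	0.431640625
E050	0.757973864574149	0.499140500780105	0.419921875
E051	-0.223044251642666	-0.885223966321178	0.408203125
E052	-0.435939993361625	0.807933451819347	0.396484375
E053	0.871897228879025	-0.302903674608674	0.384765625
E054	-0.851924104601189	-0.367506937420501	0.373046875
E055	0.381829373373068	0.850675211648673	0.361328125
E056	0.294474572462949	-0.889414420326584	0.349609375
E057	-0.821672291350416	0.45900389014045	0.337890625
E058	0.919942648655079	0.217525702261736	0.326171875
E059	-0.533628084573576	-0.785086173316071	0.314453125
E060	-0.137385400458629	0.943120962514449	0.302734375
E061	0.741195360973556	-0.604929204847262	0.291015625
E062	-0.958639011534523	-0.0548133303070215	0.279296875
E063	0.672168683187323	0.690355856326072	0.267578125
E064	-0.0294042467712202	-0.966266718094143	0.255859375
E065	-0.632997120337161	0.734649576920501	0.244140625
E066	0.965856284972528	-0.114462696109047	0.232421875
E067	-0.791723580389809	-0.569617330205091	0.220703125
E068	0.199547388229405	0.957343392339803	0.208984375
E069	0.500777977998854	-0.842797537932295	0.197265625
E070	-0.940747570514216	0.283842149353007	0.185546875
E071	0.8873393934837	0.427097862007017	0.173828125
E072	-0.366537701868512	-0.916171743531779	0.162109375
E073	-0.349246528404346	0.924883518238714	0.150390625
E074	0.883800947083134	-0.446840012777437	0.138671875
E075	-0.955035364131953	-0.267937226435749	0.126953125
E076	0.523978469050396	0.843900232723017	0.115234375
E077	0.18391944522205	-0.977475397669974	0.103515625
E078	-0.796811778399229	0.597213800530842	0.091796875
E079	0.991962275785776	0.0979711044869257	0.080078125
E080	-0.665845673491169	-0.742951233219719	0.068359375
E081	-0.0108904749501507	0.998335232852657	0.056640625
E082	0.682803331924294	-0.729219881146672	0.044921875
E083	-0.99651565571625	0.0765120931790901	0.033203125
E084	0.786735061347273	0.61691682168487	0.021484375
E085	-0.163422553273601	-0.986507831519799	0.009765625
E086	-0.545898750573489	0.837848876245017	-0.001953125
E087	0.968398861136778	-0.249031575473825	-0.013671875
E088	-0.882083593941834	-0.470408173250388	-0.025390625
E089	0.332542908229721	0.942357739116748	-0.037109375
E090	0.391149335080522	-0.919031017906931	-0.048828125
E091	-0.908633609121364	0.41318160692705	-0.060546875
E092	0.94835671625864	0.308864400943987	-0.072265625
E093	-0.490202049608997	-0.867553211806053	-0.083984375
E094	-0.224325799407072	0.969803509782065	-0.095703125
E095	0.819517549914851	-0.56289566187087	-0.107421875
E096	-0.983194184731674	-0.138328256637708	-0.119140625
E097	0.630598275830732	0.764997802934046	-0.130859375
E098	0.0516805974406371	-0.988433403988181	-0.142578125
E099	-0.704530530920297	0.692697051651296	-0.154296875
E100	0.985508797933097	-0.0348026069759482	-0.166015625
E101	-0.748636894364848	-0.638712214020615	-0.177734375
E102	0.120309463423456	0.974491224403019	-0.189453125
E103	0.568193180666293	-0.797926303710628	-0.201171875
E104	-0.955534195222714	0.204039171599942	-0.212890625
E105	0.840142600283369	0.493670983400086	-0.224609375
E106	-0.285210347784369	-0.928872475020497	-0.236328125
E107	-0.415883286723238	0.874936477481086	-0.248046875
E108	0.894819866235431	-0.363069176685058	-0.259765625
E109	-0.902035835476624	-0.335600336184051	-0.271484375
E110	0.436897312509244	0.85376620237184	-0.283203125
E111	0.253617082137457	-0.921248860674773	-0.294921875
E112	-0.806173579577928	0.506019452877179	-0.306640625
E113	0.932466321819803	0.170745035129742	-0.318359375
E114	-0.569810512535235	-0.752571864475956	-0.330078125
E115	-0.0878039327152092	0.935663062026057	-0.341796875
E116	0.69355352380529	-0.627702327937474	-0.353515625
E117	-0.930898674499863	-0.00561329963199501	-0.365234375
E118	0.67918982864625	0.629767828819646	-0.376953125
E119	-0.0750160153108804	-0.918317358559045	-0.388671875
E120	-0.561914494509368	0.723836617112171	-0.400390625
E121	0.898146961736405	-0.153290241570604	-0.412109375
E122	-0.761279904753939	-0.490736820583923	-0.423828125
E123	0.228440944342173	0.870697223279017	-0.435546875
E124	0.417014407816112	-0.791234759326925	-0.447265625
E125	-0.836357244272383	0.299733053664366	-0.458984375
E126	0.813497626373477	0.341555529892217	-0.470703125
E127	-0.366472582830921	-0.795592220018973	-0.482421875
E128	-0.26518924748313	0.827949096106724	-0.494140625
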