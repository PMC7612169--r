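snp	beta_x1	beta_x2	beta_x3	se_x1	se_x2	se_x3	beta_y	se_y
rs1	0.0623922829959626	0.0593276887893669	0.0819863895278578	0.0238828577947636	0.0239134343134387	0.023724180245148	0.0370273765549137	0.0351100171989198
rs2	0.0454897807693883	-0.0374294314657029	0.15057932582857	0.0242622752544062	0.0242944850217528	0.024027655123329	0.019666005619807	0.0355425607342814
rs3	0.109412100331051	0.037828295887735	0.0698295087446258	0.0242962807058501	0.0243691854934767	0.0241759627278273	-0.00967049996418046	0.0356539937838622
rs4	0.139498421225403	0.180752081462382	0.0528050892420808	0.0240050903259686	0.0239793575343708	0.0239265984134296	0.0875165694087767	0.0358708814230748
rs5	0.0903246424718998	0.0850903663597649	-0.000810117770743809	0.0241616987191173	0.0241948920727894	0.0240469835534261	0.0381592729328293	0.0358791605685564
rs6	0.188696929378286	0.0914185119843613	0.0504808723545822	0.0244323037912748	0.0245734848690483	0.0244164121855476	0.304008680572944	0.0351127114599476
rs7	0.141282373670887	0.0749474250589962	0.0401492980126438	0.0242246458824651	0.0243133270675522	0.0241511083154333	0.0273831873831071	0.035793281653101
rs8	0.166553729173347	0.125274837591515	0.107592533235419	0.0244758638816868	0.0245549622678042	0.024390666714565	0.0786950058615606	0.0356950591420152
rs9	0.139433657675469	0.075895928170323	0.182617686773541	0.0244891157530213	0.0245747790068532	0.0242806337556489	0.079472688862259	0.035159465714138
rs10	0.0109448901677687	0.141563381282666	0.0430256104873135	0.0242054527182116	0.0241524514259531	0.0240497153788061	0.0453322753613577	0.0351418568597505
rs11	0.0791871861366569	0.181698678591239	0.204266347340725	0.0242662491564542	0.0241853826516236	0.0239695090177942	0.0850481452243257	0.0355677353170935
rs12	0.0272670028981656	0.147019444524109	0.0656071229330184	0.0237465046207695	0.0236873400203218	0.0235856535919471	-0.0894983399235122	0.035151629972349
rs13	0.170120931991539	0.0275960501110863	0.0952299023128689	0.0241798127893643	0.0243256069148843	0.0241125554747757	0.0406153864483481	0.0359648569284268
rs14	0.0761955234384048	0.127683083459231	0.038959075186527	0.0243564003006536	0.0243429077211173	0.0242243648922282	0.00210941402967573	0.0358449944482892
rs15	0.155525230483914	0.0759307337640876	0.142489580563584	0.0241658934654061	0.024271507879238	0.0240325501099038	0.0757360018141835	0.0357678060813013
rs16	0.100673319928862	0.149942237249612	0.0725996648738319	0.0244328825053338	0.0244120792740357	0.0243024783041423	0.0790113341125113	0.0356742696376917
rs17	0.139123872996422	0.10643786207517	0.111734204461552	0.0241853823366311	0.0242480571853956	0.024064570163428	0.117338850443877	0.0359966915962912
rs18	0.236337569204624	0.200439245932278	0.166357043256177	0.023760063389447	0.0238553060522411	0.0237304709588766	0.102577795903985	0.0356878622668212
rs19	0.0886098099173939	0.0679317171145483	0.02149708068994	0.0246316984083335	0.0246747880186986	0.0245103396096548	-0.0214766043093944	0.0357709403494138
rs20	0.171009388643627	0.0620081764256447	0.158117404649615	0.0242327101488204	0.0243669060515331	0.0241001460863724	0.0716441949777618	0.035689774938306
rs21	0.138969624155143	0.169154193380086	0.028734437830448	0.0244851229086821	0.0244770384714243	0.0244097890813966	0.0643224413457556	0.0359393889368753
rs22	0.0356729908131072	-0.00789486574272727	0.134471543366078	0.0246899858262477	0.0247248512599946	0.0244697906701872	0.0855471130013775	0.0357355889598139
rs23	0.105050583124425	0.0577351612476753	0.0456691488436643	0.0249296983244181	0.0249909039297803	0.024812290247564	-0.0550647865934906	0.0350272810268815
rs24	0.0322398138781716	0.121908874013172	0.0387783643565874	0.0245898315863034	0.0245634457450473	0.0244369898541404	-0.100767825579111	0.0355476337462406
rs25	0.0738981172417755	0.109881838361551	0.100198220654028	0.0242192399130843	0.0242213809278301	0.0240513099753212	0.0430637649467536	0.0353440958104966
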