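"cas","chemical_name","chemical_group","mw_g_mol","log_kow","material","study_id","c0_ug_g","rate_ug_per_10cm2_min","contact_time_min","sample_area_cm2","sample_thickness_cm","in_vivo","agitation","product_archetype"
"0010-17-3","phthalates and alternative plasticizers compound 01","phthalates and alternative plasticizers",508.531122961082,9.62245247978717,"PVC","study_01",29114.2777783083,0.447259657293377,30,10,0.2,FALSE,TRUE,"doll"
"0010-34-4","phthalates and alternative plasticizers compound 02","phthalates and alternative plasticizers",350.107162766159,8.98268575640395,"PVC","study_02",157004.421832311,6.79056741935054,15,10,0.2,FALSE,TRUE,"doll"
"0010-51-5","phthalates and alternative plasticizers compound 03","phthalates and alternative plasticizers",439.719870761037,7.1145756947808,"PVC","study_03",60973.0452241576,2.57285833528329,60,10,0.2,FALSE,TRUE,"doll"
"0010-68-4","phthalates and alternative plasticizers compound 04","phthalates and alternative plasticizers",463.620255289599,4.80799958342686,"PVC","study_01",56802.0986546148,1.71056486479486,15,10,0.2,FALSE,TRUE,"doll"
"0010-85-5","phthalates and alternative plasticizers compound 05","phthalates and alternative plasticizers",443.562057181261,8.2303887042217,"PVC","study_02",15600.3193250376,0.199963533225125,15,10,0.2,FALSE,TRUE,"doll"
"0011-02-9","phthalates and alternative plasticizers compound 06","phthalates and alternative plasticizers",393.350927614607,8.31467350991443,"PVC","study_03",90020.5947757282,0.26507836863735,60,10,0.2,FALSE,TRUE,"doll"
"0011-19-8","phthalates and alternative plasticizers compound 07","phthalates and alternative plasticizers",513.537406282499,5.53257294604555,"PVC","study_01",24099.7992566913,0.363408711173672,30,10,0.2,FALSE,TRUE,"doll"
"0011-36-9","phthalates and alternative plasticizers compound 08","phthalates and alternative plasticizers",394.49779128097,9.64008713653311,"PVC","study_02",103099.015571619,0.76914347636872,60,10,0.2,FALSE,TRUE,"doll"
"0011-53-0","phthalates and alternative plasticizers compound 09","phthalates and alternative plasticizers",524.513059953228,4.70492416992784,"PVC","study_03",17555.9065943022,0.0260237496635867,60,10,0.2,FALSE,TRUE,"doll"
"0011-70-1","phthalates and alternative plasticizers compound 10","phthalates and alternative plasticizers",397.699264553376,7.3619964774698,"PVC","study_01",164525.304589546,2.70961890398183,30,10,0.2,FALSE,TRUE,"doll"
"0011-87-0","phthalates and alternative plasticizers compound 11","phthalates and alternative plasticizers",505.815909598954,4.83226100634784,"PVC","study_02",49700.2856838604,0.161284824425555,60,10,0.2,FALSE,TRUE,"doll"
"0012-04-4","phthalates and alternative plasticizers compound 12","phthalates and alternative plasticizers",527.200715688057,9.68000939534977,"PVC","study_03",17463.2265528241,0.141718383043646,15,10,0.2,FALSE,TRUE,"doll"
"0012-21-5","phthalates and alternative plasticizers compound 13","phthalates and alternative plasticizers",298.774264641106,7.08527070609853,"PVC","study_01",35990.1057490533,2.15849954468445,30,10,0.2,FALSE,TRUE,"doll"
"0012-38-4","phthalates and alternative plasticizers compound 14","phthalates and alternative plasticizers",376.331273710355,9.43442878546193,"PVC","study_02",108027.492716699,3.70952104791297,30,10,0.2,FALSE,TRUE,"doll"
"0012-55-5","phthalates and alternative plasticizers compound 15","phthalates and alternative plasticizers",390.636346281506,9.0160255599767,"PVC","study_03",21742.3151297947,0.571867173256242,30,10,0.2,FALSE,TRUE,"doll"
"0012-72-6","phthalates and alternative plasticizers compound 16","phthalates and alternative plasticizers",463.874095678329,8.86633084760979,"PVC","study_01",107637.984098528,0.524050872911617,30,10,0.2,FALSE,TRUE,"doll"
"0012-89-5","parabens compound 01","parabens",168.300547878258,3.02775459410623,"EVA","study_04",2148.71255409997,0.212388919602584,30,10,0.25,FALSE,FALSE,"pacifier"
"0013-06-9","parabens compound 02","parabens",152.165830229409,3.2493741203798,"EVA","study_05",123.102082184925,0.0175872509267728,15,10,0.25,FALSE,FALSE,"pacifier"
"0013-23-0","parabens compound 03","parabens",152.308034169022,2.31148845923599,"EVA","study_06",1747.76508657787,4.39819495375508,30,10,0.25,FALSE,FALSE,"pacifier"
"0013-40-1","parabens compound 04","parabens",190.077259127516,2.91766796517186,"EVA","study_04",185.452868377541,1.26242076587232,15,10,0.25,FALSE,FALSE,"pacifier"
"0013-57-0","parabens compound 05","parabens",167.941488102544,2.6536573774647,"EVA","study_05",268.48456036443,0.222668923653854,30,10,0.25,FALSE,FALSE,"pacifier"
"0013-74-1","parabens compound 06","parabens",153.572103380226,3.46030987065751,"EVA","study_06",126.926349829474,0.0927853756433767,30,10,0.25,FALSE,FALSE,"pacifier"
"0013-91-2","parabens compound 07","parabens",170.133552453481,3.43636489496566,"EVA","study_04",398.411340887346,0.793324757185438,15,10,0.25,FALSE,FALSE,"pacifier"
"0014-08-4","parabens compound 08","parabens",189.285706031136,2.95996815420222,"EVA","study_05",195.70314820613,1.16286507570027,15,10,0.25,FALSE,FALSE,"pacifier"
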