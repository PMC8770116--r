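"chemical_key","rfd_ug_per_kg_d","source"
"0010-17-3",555,"experimental"
"0010-34-4",647,"qsar_predicted"
"0010-51-5",7.22,"experimental"
"0010-68-4",310,"experimental"
"0010-85-5",84.2,"experimental"
"0011-02-9",36.1,"experimental"
"0011-19-8",162,"qsar_predicted"
"0011-36-9",2.54,"qsar_predicted"
"0011-53-0",93.5,"qsar_predicted"
"0011-70-1",130,"qsar_predicted"
"0011-87-0",23.6,"experimental"
"0012-04-4",144,"qsar_predicted"
"0012-21-5",637,"experimental"
"0012-38-4",5.84,"qsar_predicted"
"0012-55-5",24.4,"qsar_predicted"
"0012-72-6",661,"qsar_predicted"
"0012-89-5",860,"experimental"
"0013-06-9",2.25,"experimental"
"0013-23-0",26.6,"qsar_predicted"
"0013-40-1",48,"qsar_predicted"
"0013-57-0",515,"qsar_predicted"
"0013-74-1",2.61,"qsar_predicted"
"0013-91-2",926,"qsar_predicted"
"0014-08-4",692,"qsar_predicted"
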