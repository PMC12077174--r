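sample_id	level_a	taxon_a	level_b	taxon_b
iso001	no_id	NA	no_id	NA
iso002	no_id	NA	family	NA
iso003	no_id	NA	family	NA
iso004	no_id	NA	genus	NA
iso005	no_id	NA	genus	NA
iso006	no_id	NA	genus	NA
iso007	no_id	NA	genus	NA
iso008	no_id	NA	species	NA
iso009	family	NA	family	NA
iso010	family	NA	family	NA
iso011	family	NA	family	NA
iso012	family	NA	family	NA
iso013	family	NA	genus	NA
iso014	family	NA	genus	NA
iso015	family	NA	genus	NA
iso016	family	NA	genus	NA
iso017	family	NA	genus	NA
iso018	family	NA	genus	NA
iso019	genus	NA	family	NA
iso020	genus	NA	genus	NA
iso021	genus	NA	genus	NA
iso022	genus	NA	genus	NA
iso023	genus	NA	genus	NA
iso024	genus	NA	genus	NA
iso025	genus	NA	genus	NA
iso026	genus	NA	genus	NA
iso027	genus	NA	genus	NA
iso028	genus	NA	genus	NA
iso029	genus	NA	genus	NA
iso030	genus	NA	genus	NA
iso031	genus	NA	genus	NA
iso032	genus	NA	genus	NA
iso033	genus	NA	genus	NA
iso034	genus	NA	genus	NA
iso035	genus	NA	genus	NA
iso036	genus	NA	species	NA
iso037	genus	NA	species	NA
iso038	genus	NA	species	NA
iso039	genus	NA	species	NA
iso040	genus	NA	species	NA
iso041	genus	NA	species	NA
iso042	genus	NA	species	NA
iso043	genus	NA	species	NA
iso044	genus	NA	species	NA
iso045	genus	NA	species	NA
iso046	genus	NA	species	NA
iso047	genus	NA	species	NA
iso048	genus	NA	species	NA
iso049	genus	NA	species	NA
iso050	genus	NA	species	NA
iso051	species	NA	genus	NA
iso052	species	NA	genus	NA
iso053	species	NA	genus	NA
iso054	species	NA	genus	NA
iso055	species	NA	genus	NA
iso056	species	NA	genus	NA
iso057	species	NA	genus	NA
iso058	species	NA	genus	NA
iso059	species	NA	species	NA
iso060	species	NA	species	NA
iso061	species	NA	species	NA
iso062	species	NA	species	NA
iso063	species	NA	species	NA
iso064	species	NA	species	NA
iso065	species	NA	species	NA
iso066	species	NA	species	NA
iso067	species	NA	species	NA
iso068	species	NA	species	NA
iso069	species	NA	species	NA
iso070	species	NA	species	NA
iso071	species	NA	species	NA
iso072	species	NA	species	NA
iso073	species	NA	species	NA
iso074	species	NA	species	NA
iso075	species	NA	species	NA
iso076	species	NA	species	NA
iso077	species	NA	species	NA
iso078	species	NA	species	NA
iso079	species	NA	species	NA
iso080	species	NA	species	NA
iso081	species	NA	species	NA
iso082	species	NA	species	NA
iso083	species	NA	species	NA
iso084	species	NA	species	NA
iso085	species	NA	species	NA
iso086	species	NA	species	NA
iso087	species	NA	species	NA
iso088	species	NA	species	NA
iso089	species	NA	species	NA
iso090	species	NA	species	NA
iso091	species	NA	species	NA
iso092	species	NA	species	NA
iso093	species	NA	species	NA
iso094	species	NA	species	NA
iso095	species	NA	species	NA
iso096	species	NA	species	NA
iso097	species	NA	species	NA
iso098	species	NA	species	NA
iso099	species	NA	species	NA
iso100	species	NA	species	NA
iso101	species	NA	species	NA
iso102	species	NA	species	NA
iso103	species	NA	species	NA
iso104	species	NA	species	NA
iso105	species	NA	species	NA
iso106	species	NA	species	NA
iso107	species	NA	species	NA
iso108	species	NA	species	NA
iso109	species	NA	species	NA
iso110	species	NA	species	NA
iso111	species	NA	species	NA
iso112	species	NA	species	NA
iso113	species	NA	species	NA
iso114	species	NA	species	NA
iso115	species	NA	species	NA
iso116	species	NA	species	NA
iso117	species	NA	species	NA
iso118	species	NA	species	NA
iso119	species	NA	species	NA
iso120	species	NA	species	NA
iso121	species	NA	species	NA
iso122	species	NA	species	NA
iso123	species	NA	species	NA
iso124	species	NA	species	NA
iso125	species	NA	species	NA
iso126	species	NA	species	NA
iso127	species	NA	species	NA
iso128	species	NA	species	NA
iso129	species	NA	species	NA
iso130	species	NA	species	NA
iso131	species	NA	species	NA
iso132	species	NA	species	NA
iso133	species	NA	species	NA
iso134	species	NA	species	NA
iso135	species	NA	species	NA
iso136	species	NA	species	NA
iso137	species	NA	species	NA
iso138	species	NA	species	NA
iso139	species	NA	species	NA
iso140	species	NA	species	NA
iso141	species	NA	species	NA
iso142	species	NA	species	NA
iso143	species	NA	species	NA
iso144	species	NA	species	NA
iso145	species	NA	species	NA
iso146	species	NA	species	NA
iso147	species	NA	species	NA
iso148	species	NA	species	NA
iso149	species	NA	species	NA
iso150	species	NA	species	NA
iso151	species	NA	species	NA
iso152	species	NA	species	NA
iso153	species	NA	species	NA
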