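path_01	Toy pathway 01	met_017	met_006	met_046	met_053	met_055	met_098	met_101	met_115	met_072	met_045	met_008	met_038	met_113	met_076	met_048	met_118
path_02	Toy pathway 02	met_088	met_027	met_003	met_120	met_025	met_104	met_094	met_058	met_081	met_089	met_006	met_093
path_03	Toy pathway 03	met_011	met_026	met_061	met_103	met_025	met_088	met_033	met_089	met_107	met_094	met_029
path_04	Toy pathway 04	met_108	met_073	met_072	met_096	met_016	met_066	met_044	met_012	met_091	met_113	met_099	met_029	met_054	met_118
path_05	Toy pathway 05	met_099	met_007	met_076	met_119	met_095	met_109	met_041	met_052	met_018	met_111	met_064	met_066	met_054	met_098	met_112	met_044	met_039	met_049	met_073
path_06	Toy pathway 06	met_011	met_035	met_049	met_084	met_082	met_013	met_057	met_067	met_004	met_034	met_039	met_041	met_008	met_120	met_030	met_029	met_081	met_087
path_07	Toy pathway 07	met_039	met_075	met_030	met_062	met_082	met_096	met_002	met_031
path_08	Toy pathway 08	met_084	met_027	met_112	met_016	met_109	met_050	met_078	met_074	met_002	met_026	met_052	met_038	met_100	met_067	met_042	met_041	met_048	met_066	met_118
path_09	Toy pathway 09	met_061	met_083	met_042	met_033	met_103	met_058	met_057	met_077	met_008
path_10	Toy pathway 10	met_110	met_075	met_035	met_062	met_085	met_050	met_076	met_090	met_044
path_11	Toy pathway 11	met_091	met_054	met_027	met_001	met_065	met_082	met_026	met_088	met_023	met_064	met_013	met_006	met_108	met_086	met_029	met_059	met_097	met_101	met_103	met_117
path_12	Toy pathway 12	met_005	met_106	met_089	met_077	met_024	met_027	met_071	met_010	met_117	met_086	met_097	met_017
path_13	Toy pathway 13	met_030	met_048	met_023	met_088	met_073	met_005	met_011	met_115
path_14	Toy pathway 14	met_077	met_043	met_103	met_068	met_081	met_025	met_106	met_101	met_056	met_018	met_019	met_045	met_046	met_102	met_010	met_026	met_088	met_072
path_15	Toy pathway 15	met_080	met_106	met_104	met_010	met_009	met_086	met_006	met_008	met_057	met_078	met_098	met_068	met_115	met_030	met_037	met_011	met_028	met_025	met_045	met_054
path_16	Toy pathway 16	met_042	met_040	met_117	met_013	met_061	met_018	met_055	met_095	met_046	met_005	met_065	met_107	met_094	met_096	met_049	met_114	met_118	met_004
path_17	Toy pathway 17	met_096	met_029	met_036	met_062	met_080	met_006	met_059	met_108	met_014	met_086	met_021	met_068	met_120	met_039	met_045
path_18	Toy pathway 18	met_045	met_022	met_100	met_024	met_001	met_027	met_076	met_010	met_005
path_19	Toy pathway 19	met_111	met_062	met_030	met_057	met_105	met_101	met_012	met_086	met_029	met_026	met_032	met_118	met_117
path_20	Toy pathway 20	met_092	met_066	met_046	met_036	met_064	met_104	met_106	met_089	met_113	met_002	met_044	met_043	met_101	met_042	met_077	met_063	met_090
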