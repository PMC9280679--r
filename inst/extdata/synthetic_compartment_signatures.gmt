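AG	synthetic_compartment	AG_001	AG_002	AG_003	AG_004	AG_005	AG_006	AG_007	AG_008	AG_009	AG_010	AG_011	AG_012	AG_013	AG_014	AG_015	AG_016	AG_017	AG_018	AG_019	AG_020	AG_021	AG_022	AG_023	AG_024	AG_025	AG_026	AG_027	AG_028	AG_029	AG_030
SG	synthetic_compartment	SG_001	SG_002	SG_003	SG_004	SG_005	SG_006	SG_007	SG_008	SG_009	SG_010	SG_011	SG_012	SG_013	SG_014	SG_015	SG_016	SG_017	SG_018	SG_019	SG_020	SG_021	SG_022	SG_023	SG_024	SG_025	SG_026	SG_027	SG_028	SG_029	SG_030
GG	synthetic_compartment	GG_001	GG_002	GG_003	GG_004	GG_005	GG_006	GG_007	GG_008	GG_009	GG_010	GG_011	GG_012
FG	synthetic_compartment	FG_001	FG_002	FG_003	FG_004	FG_005	FG_006	FG_007	FG_008	FG_009	FG_010	FG_011	FG_012	FG_013	FG_014	FG_015	FG_016	FG_017	FG_018	FG_019	FG_020
SV	synthetic_compartment	SV_001	SV_002	SV_003	SV_004	SV_005	SV_006	SV_007	SV_008	SV_009	SV_010	SV_011	SV_012	SV_013	SV_014	SV_015	SV_016	SV_017	SV_018	SV_019	SV_020
CM	synthetic_compartment	CM_001	CM_002	CM_003	CM_004	CM_005	CM_006	CM_007	CM_008	CM_009	CM_010	CM_011	CM_012	CM_013	CM_014	CM_015	CM_016	CM_017	CM_018	CM_019	CM_020	CM_021	CM_022	CM_023	CM_024	CM_025	CM_026	CM_027	CM_028	CM_029	CM_030	CM_031	CM_032	CM_033	CM_034	CM_035	CM_036	CM_037	CM_038	CM_039	CM_040
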