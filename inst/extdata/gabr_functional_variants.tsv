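gene	variant	phenotype_group	polyphen_category	humdiv_score	humvar_score	domain	reduced_current	gating_defect	interface_side
GABRA1	T20I	GEC	benign	0.001	0.003	SP	no	yes	none
GABRA4	H372P	GEC	benign	0.0	0.0	CL	yes	no	none
GABRA5	W280R	GEC	damaging	1.0	0.999	TM	yes	yes	complementary
GABRA5	P453L	GEC	possibly	0.515	0.117	TM	no	yes	none
GABRB2	R293W	GEC	damaging	1.0	1.0	TM	yes	yes	principal
GABRG3	A303T	GEC	damaging	0.999	0.966	TM	yes	yes	none
GABRA4	A19T	GEC	benign	0.001	0.001	SP	no	no	none
GABRA5	V204I	GEC	benign	0.001	0.005	NT	yes	yes	complementary
GABRA5	S402A	GEC	benign	0.0	0.004	CL	no	no	none
GABRA6	Q237R	GEC	benign	0.041	0.06	NT	yes	yes	complementary
GABRB1	H421Q	GEC	benign	0.002	0.006	CL	no	no	none
GABRB2	R354C	GEC	damaging	0.999	0.892	CL	yes	yes	none
GABRG1	S16R	GEC	benign	0.023	0.029	SP	no	no	none
GABRG1	S414N	GEC	possibly	0.57	0.334	CL	no	no	none
GABRA1	D9E	ESP	benign	0.0	0.0	SP	no	no	none
GABRA1	P29S	ESP	benign	0.02	0.01	NT	yes	no	complementary
GABRA1	H129Y	ESP	damaging	0.976	0.880	NT	yes	no	principal
GABRA1	R147W	ESP	damaging	1.0	1.0	NT	no	yes	complementary
GABRA1	T371I	ESP	benign	0.237	0.119	CL	no	no	none
GABRA1	D383N	ESP	benign	0.165	0.024	CL	no	no	none
GABRA1	P409S	ESP	benign	0.005	0.011	CL	yes	no	none
GABRA1	K410R	ESP	benign	0.121	0.069	CL	no	no	none
GABRA1	T441M	ESP	damaging	1.0	0.999	TM	yes	yes	principal
GABRB3	R194Q	ESP	benign	0.016	0.009	NT	yes	yes	complementary
GABRB3	D197N	ESP	benign	0.001	0.006	NT	no	yes	complementary
GABRB3	V200I	ESP	damaging	0.945	0.646	NT	yes	no	complementary
GABRB3	R221K	ESP	benign	0.0	0.002	NT	yes	yes	principal
GABRB3	R238W	ESP	benign	0.161	0.033	NT	yes	yes	principal
GABRB3	D387N	ESP	benign	0.03	0.027	CL	yes	yes	none
GABRB3	I448V	ESP	damaging	0.718	0.447	TM	yes	no	complementary
GABRG2	L57F	ESP	damaging	0.995	0.962	NT	yes	no	complementary
GABRG2	A402T	ESP	possibly	0.534	0.205	CL	no	no	none
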