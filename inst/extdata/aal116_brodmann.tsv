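# AAL-116 parcellation with Brodmann-area annotations, v1.
# Compiled from published AAL-region/Brodmann-area pairings for this
# pipeline's region reporting, completed with standard AAL documentation
# assignments for the remaining cortical parcels. Cerebellar hemispheric
# lobules, vermis subdivisions and deep grey-matter nuclei carry "-"
# (no cytoarchitectonic Brodmann assignment). Left/right homologues share
# one annotation.
aal_index	aal_name	brodmann
1	Precentral_L	4
2	Precentral_R	4
3	Frontal_Sup_L	11, 12
4	Frontal_Sup_R	11, 12
5	Frontal_Sup_Orb_L	11
6	Frontal_Sup_Orb_R	11
7	Frontal_Mid_L	9, 46
8	Frontal_Mid_R	9, 46
9	Frontal_Mid_Orb_L	11, 12
10	Frontal_Mid_Orb_R	11, 12
11	Frontal_Inf_Oper_L	44
12	Frontal_Inf_Oper_R	44
13	Frontal_Inf_Tri_L	44, 45
14	Frontal_Inf_Tri_R	44, 45
15	Frontal_Inf_Orb_L	47
16	Frontal_Inf_Orb_R	47
17	Rolandic_Oper_L	43
18	Rolandic_Oper_R	43
19	Supp_Motor_Area_L	6
20	Supp_Motor_Area_R	6
21	Olfactory_L	25
22	Olfactory_R	25
23	Frontal_Sup_Medial_L	11, 12
24	Frontal_Sup_Medial_R	11, 12
25	Frontal_Med_Orb_L	10, 11
26	Frontal_Med_Orb_R	10, 11
27	Rectus_L	11, 12
28	Rectus_R	11, 12
29	Insula_L	13, 16
30	Insula_R	13, 16
31	Cingulum_Ant_L	24, 32
32	Cingulum_Ant_R	24, 32
33	Cingulum_Mid_L	23, 24
34	Cingulum_Mid_R	23, 24
35	Cingulum_Post_L	23, 31
36	Cingulum_Post_R	23, 31
37	Hippocampus_L	28, 35
38	Hippocampus_R	28, 35
39	ParaHippocampal_L	34
40	ParaHippocampal_R	34
41	Amygdala_L	34
42	Amygdala_R	34
43	Calcarine_L	17
44	Calcarine_R	17
45	Cuneus_L	17, 18
46	Cuneus_R	17, 18
47	Lingual_L	17
48	Lingual_R	17
49	Occipital_Sup_L	17
50	Occipital_Sup_R	17
51	Occipital_Mid_L	17
52	Occipital_Mid_R	17
53	Occipital_Inf_L	18, 19
54	Occipital_Inf_R	18, 19
55	Fusiform_L	37
56	Fusiform_R	37
57	Postcentral_L	1, 2, 3
58	Postcentral_R	1, 2, 3
59	Parietal_Sup_L	5, 7
60	Parietal_Sup_R	5, 7
61	Parietal_Inf_L	5
62	Parietal_Inf_R	5
63	SupraMarginal_L	40
64	SupraMarginal_R	40
65	Angular_L	39
66	Angular_R	39
67	Precuneus_L	7
68	Precuneus_R	7
69	Paracentral_Lobule_L	4, 5
70	Paracentral_Lobule_R	4, 5
71	Caudate_L	-
72	Caudate_R	-
73	Putamen_L	-
74	Putamen_R	-
75	Pallidum_L	-
76	Pallidum_R	-
77	Thalamus_L	41, 42
78	Thalamus_R	41, 42
79	Heschl_L	41
80	Heschl_R	41
81	Temporal_Sup_L	22, 41, 42
82	Temporal_Sup_R	22, 41, 42
83	Temporal_Pole_Sup_L	38
84	Temporal_Pole_Sup_R	38
85	Temporal_Mid_L	21
86	Temporal_Mid_R	21
87	Temporal_Pole_Mid_L	38
88	Temporal_Pole_Mid_R	38
89	Temporal_Inf_L	20
90	Temporal_Inf_R	20
91	Cerebelum_Crus1_L	-
92	Cerebelum_Crus1_R	-
93	Cerebelum_Crus2_L	-
94	Cerebelum_Crus2_R	-
95	Cerebelum_3_L	-
96	Cerebelum_3_R	-
97	Cerebelum_4_5_L	-
98	Cerebelum_4_5_R	-
99	Cerebelum_6_L	-
100	Cerebelum_6_R	-
101	Cerebelum_7b_L	-
102	Cerebelum_7b_R	-
103	Cerebelum_8_L	-
104	Cerebelum_8_R	-
105	Cerebelum_9_L	-
106	Cerebelum_9_R	-
107	Cerebelum_10_L	-
108	Cerebelum_10_R	-
109	Vermis_1_2	-
110	Vermis_3	-
111	Vermis_4_5	-
112	Vermis_6	-
113	Vermis_7	-
114	Vermis_8	-
115	Vermis_9	-
116	Vermis_10	-
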