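index,name,hemisphere,lobe
1,Precentral_L,L,frontal
2,Precentral_R,R,frontal
3,Frontal_Sup_L,L,frontal
4,Frontal_Sup_R,R,frontal
5,Frontal_Sup_Orb_L,L,frontal
6,Frontal_Sup_Orb_R,R,frontal
7,Frontal_Mid_L,L,frontal
8,Frontal_Mid_R,R,frontal
9,Frontal_Mid_Orb_L,L,frontal
10,Frontal_Mid_Orb_R,R,frontal
11,Frontal_Inf_Oper_L,L,frontal
12,Frontal_Inf_Oper_R,R,frontal
13,Frontal_Inf_Tri_L,L,frontal
14,Frontal_Inf_Tri_R,R,frontal
15,Frontal_Inf_Orb_L,L,frontal
16,Frontal_Inf_Orb_R,R,frontal
17,Rolandic_Oper_L,L,frontal
18,Rolandic_Oper_R,R,frontal
19,Supp_Motor_Area_L,L,frontal
20,Supp_Motor_Area_R,R,frontal
21,Olfactory_L,L,frontal
22,Olfactory_R,R,frontal
23,Frontal_Sup_Medial_L,L,frontal
24,Frontal_Sup_Medial_R,R,frontal
25,Frontal_Med_Orb_L,L,frontal
26,Frontal_Med_Orb_R,R,frontal
27,Rectus_L,L,frontal
28,Rectus_R,R,frontal
29,Insula_L,L,subcortical
30,Insula_R,R,subcortical
31,Cingulum_Ant_L,L,subcortical
32,Cingulum_Ant_R,R,subcortical
33,Cingulum_Mid_L,L,subcortical
34,Cingulum_Mid_R,R,subcortical
35,Cingulum_Post_L,L,subcortical
36,Cingulum_Post_R,R,subcortical
37,Hippocampus_L,L,medial temporal
38,Hippocampus_R,R,medial temporal
39,ParaHippocampal_L,L,medial temporal
40,ParaHippocampal_R,R,medial temporal
41,Amygdala_L,L,medial temporal
42,Amygdala_R,R,medial temporal
43,Calcarine_L,L,occipital
44,Calcarine_R,R,occipital
45,Cuneus_L,L,occipital
46,Cuneus_R,R,occipital
47,Lingual_L,L,occipital
48,Lingual_R,R,occipital
49,Occipital_Sup_L,L,occipital
50,Occipital_Sup_R,R,occipital
51,Occipital_Mid_L,L,occipital
52,Occipital_Mid_R,R,occipital
53,Occipital_Inf_L,L,occipital
54,Occipital_Inf_R,R,occipital
55,Fusiform_L,L,occipital
56,Fusiform_R,R,occipital
57,Postcentral_L,L,parietal
58,Postcentral_R,R,parietal
59,Parietal_Sup_L,L,parietal
60,Parietal_Sup_R,R,parietal
61,Parietal_Inf_L,L,parietal
62,Parietal_Inf_R,R,parietal
63,SupraMarginal_L,L,parietal
64,SupraMarginal_R,R,parietal
65,Angular_L,L,parietal
66,Angular_R,R,parietal
67,Precuneus_L,L,parietal
68,Precuneus_R,R,parietal
69,Paracentral_Lobule_L,L,frontal
70,Paracentral_Lobule_R,R,frontal
71,Caudate_L,L,subcortical
72,Caudate_R,R,subcortical
73,Putamen_L,L,subcortical
74,Putamen_R,R,subcortical
75,Pallidum_L,L,subcortical
76,Pallidum_R,R,subcortical
77,Thalamus_L,L,subcortical
78,Thalamus_R,R,subcortical
79,Heschl_L,L,temporal
80,Heschl_R,R,temporal
81,Temporal_Sup_L,L,temporal
82,Temporal_Sup_R,R,temporal
83,Temporal_Pole_Sup_L,L,temporal
84,Temporal_Pole_Sup_R,R,temporal
85,Temporal_Mid_L,L,temporal
86,Temporal_Mid_R,R,temporal
87,Temporal_Pole_Mid_L,L,temporal
88,Temporal_Pole_Mid_R,R,temporal
89,Temporal_Inf_L,L,temporal
90,Temporal_Inf_R,R,temporal
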