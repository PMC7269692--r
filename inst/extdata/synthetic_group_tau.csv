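"region_id","region","tau"
0,"middle frontal gyrus",0.218
1,"posterior cingulate cortex",0.18
2,"hippocampus",0.197
3,"cuneal cortex",0.184
4,"inferior lateral occipital cortex",0.158
5,"superior lateral occipital cortex",0.158
6,"occipital fusiform gyrus",0.169
7,"temporal fusiform cortex",0.164
8,"temporo-occipital fusiform cortex",0.18
9,"angular gyrus",0.184
10,"precuneus",0.249
11,"superior parietal lobule",0.243
12,"posterior supramarginal gyrus",0.227
13,"anterior inferior temporal gyrus",0.2
14,"posterior inferior temporal gyrus",0.178
15,"temporo-occipital inferior temporal gyrus",0.207
16,"anterior middle temporal gyrus",0.161
17,"posterior middle temporal gyrus",0.196
18,"temporo-occipital middle temporal gyrus",0.205
19,"anterior superior temporal gyrus",0.178
20,"posterior superior temporal gyrus",0.159
21,"frontal pole",0.089
22,"superior frontal gyrus",0.076
23,"inferior frontal gyrus pars triangularis",0.09
24,"inferior frontal gyrus pars opercularis",0.085
25,"precentral gyrus",0.116
26,"frontal medial cortex",0.118
27,"supplementary motor cortex",0.107
28,"frontal orbital cortex",0.113
29,"frontal operculum cortex",0.099
30,"central opercular cortex",0.098
31,"paracingulate gyrus",0.078
32,"anterior cingulate cortex",0.087
33,"subcallosal cortex",0.064
34,"insular cortex",0.08
35,"parahippocampal gyrus anterior",0.106
36,"parahippocampal gyrus posterior",0.107
37,"temporal pole",0.066
38,"planum polare",0.065
39,"heschl's gyrus",0.074
40,"planum temporale",0.084
41,"postcentral gyrus",0.09
42,"anterior supramarginal gyrus",0.118
43,"parietal operculum cortex",0.121
44,"intracalcarine cortex",0.074
45,"supracalcarine cortex",0.119
46,"lingual gyrus",0.064
47,"occipital pole",0.08
48,"subcentral cortex",0.093
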