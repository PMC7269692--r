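name	hemisphere	lobe	region_id
middle frontal gyrus	L	frontal	0
middle frontal gyrus	R	frontal	0
posterior cingulate cortex	L	limbic	1
posterior cingulate cortex	R	limbic	1
hippocampus	L	limbic	2
hippocampus	R	limbic	2
cuneal cortex	L	occipital	3
cuneal cortex	R	occipital	3
inferior lateral occipital cortex	L	occipital	4
inferior lateral occipital cortex	R	occipital	4
superior lateral occipital cortex	L	occipital	5
superior lateral occipital cortex	R	occipital	5
occipital fusiform gyrus	L	occipital	6
occipital fusiform gyrus	R	occipital	6
temporal fusiform cortex	L	temporal	7
temporal fusiform cortex	R	temporal	7
temporo-occipital fusiform cortex	L	temporal	8
temporo-occipital fusiform cortex	R	temporal	8
angular gyrus	L	parietal	9
angular gyrus	R	parietal	9
precuneus	L	parietal	10
precuneus	R	parietal	10
superior parietal lobule	L	parietal	11
superior parietal lobule	R	parietal	11
posterior supramarginal gyrus	L	parietal	12
posterior supramarginal gyrus	R	parietal	12
anterior inferior temporal gyrus	L	temporal	13
anterior inferior temporal gyrus	R	temporal	13
posterior inferior temporal gyrus	L	temporal	14
posterior inferior temporal gyrus	R	temporal	14
temporo-occipital inferior temporal gyrus	L	temporal	15
temporo-occipital inferior temporal gyrus	R	temporal	15
anterior middle temporal gyrus	L	temporal	16
anterior middle temporal gyrus	R	temporal	16
posterior middle temporal gyrus	L	temporal	17
posterior middle temporal gyrus	R	temporal	17
temporo-occipital middle temporal gyrus	L	temporal	18
temporo-occipital middle temporal gyrus	R	temporal	18
anterior superior temporal gyrus	L	temporal	19
anterior superior temporal gyrus	R	temporal	19
posterior superior temporal gyrus	L	temporal	20
posterior superior temporal gyrus	R	temporal	20
frontal pole	L	frontal	21
frontal pole	R	frontal	21
superior frontal gyrus	L	frontal	22
superior frontal gyrus	R	frontal	22
inferior frontal gyrus pars triangularis	L	frontal	23
inferior frontal gyrus pars triangularis	R	frontal	23
inferior frontal gyrus pars opercularis	L	frontal	24
inferior frontal gyrus pars opercularis	R	frontal	24
precentral gyrus	L	frontal	25
precentral gyrus	R	frontal	25
frontal medial cortex	L	frontal	26
frontal medial cortex	R	frontal	26
supplementary motor cortex	L	frontal	27
supplementary motor cortex	R	frontal	27
frontal orbital cortex	L	frontal	28
frontal orbital cortex	R	frontal	28
frontal operculum cortex	L	frontal	29
frontal operculum cortex	R	frontal	29
central opercular cortex	L	frontal	30
central opercular cortex	R	frontal	30
paracingulate gyrus	L	limbic	31
paracingulate gyrus	R	limbic	31
anterior cingulate cortex	L	limbic	32
anterior cingulate cortex	R	limbic	32
subcallosal cortex	L	limbic	33
subcallosal cortex	R	limbic	33
insular cortex	L	limbic	34
insular cortex	R	limbic	34
parahippocampal gyrus anterior	L	limbic	35
parahippocampal gyrus anterior	R	limbic	35
parahippocampal gyrus posterior	L	limbic	36
parahippocampal gyrus posterior	R	limbic	36
temporal pole	L	temporal	37
temporal pole	R	temporal	37
planum polare	L	temporal	38
planum polare	R	temporal	38
heschl's gyrus	L	temporal	39
heschl's gyrus	R	temporal	39
planum temporale	L	temporal	40
planum temporale	R	temporal	40
postcentral gyrus	L	parietal	41
postcentral gyrus	R	parietal	41
anterior supramarginal gyrus	L	parietal	42
anterior supramarginal gyrus	R	parietal	42
parietal operculum cortex	L	parietal	43
parietal operculum cortex	R	parietal	43
intracalcarine cortex	L	occipital	44
intracalcarine cortex	R	occipital	44
supracalcarine cortex	L	occipital	45
supracalcarine cortex	R	occipital	45
lingual gyrus	L	occipital	46
lingual gyrus	R	occipital	46
occipital pole	L	occipital	47
occipital pole	R	occipital	47
subcentral cortex	L	frontal	48
subcentral cortex	R	frontal	48
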