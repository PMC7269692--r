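name	hemisphere	lobe	region_id
frontal a	L	frontal	0
frontal a	R	frontal	0
frontal b	L	frontal	1
frontal b	R	frontal	1
frontal c	L	frontal	2
frontal c	R	frontal	2
temporal a	L	temporal	3
temporal a	R	temporal	3
temporal b	L	temporal	4
temporal b	R	temporal	4
temporal c	L	temporal	5
temporal c	R	temporal	5
parietal a	L	parietal	6
parietal a	R	parietal	6
parietal b	L	parietal	7
parietal b	R	parietal	7
occipital a	L	occipital	8
occipital a	R	occipital	8
occipital b	L	occipital	9
occipital b	R	occipital	9
limbic a	L	limbic	10
limbic a	R	limbic	10
limbic b	L	limbic	11
limbic b	R	limbic	11
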