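primary_morphospecies	secondary_species	mb_base	clade_letters	origin	cryptic	n_coi	n_16s
Flabelligena sp. A	Flabelligena sp. A (MB)	MB		retained	FALSE	8	12
Flabelligena sp. B	Flabelligena sp. B (MB)	MB		retained	FALSE	2	8
Chaetozone sp. A	Chaetozone sp. (MB1a-c)	MB1	a-c	retained	FALSE	0	10
Euphrosinella cirratoformis	Euphrosinella cf. cirratoformis (MB1)	MB1		retained	TRUE	0	10
Euphrosinella cirratoformis	Euphrosinella cf. cirratoformis (MB2)	MB2		cryptic_split	TRUE	0	3
Euphrosinella cirratoformis	Euphrosinopsis cf. antarctica (MB)	MB		reassignment	FALSE	0	2
Glycera capitata	Glycera sp. (MB1)	MB1		retained	TRUE	4	15
Glycera capitata	Glycera sp. (MB2)	MB2		cryptic_split	TRUE	9	17
Hesionidae sp. A	Hesionidae sp. (MB1)	MB1		retained	TRUE	5	24
Hesionidae sp. A	Hesionidae sp. (MB2)	MB2		cryptic_split	TRUE	8	NA
Lumbrineris kerguelensis-cingulata	Lumbrineris kerguelensis-cingulata (MB1a-f)	MB1	a-f	retained	FALSE	0	16
Maldane sarsi	Asychis amphiglyptus (MB)	MB		reassignment	FALSE	0	4
Maldane sarsi	Eupraxillella cf. antarctica (MB)	MB		reassignment	FALSE	0	5
Maldane sarsi	Maldane sarsi antarctica (MB)	MB		retained	TRUE	0	2
Maldane sarsi	Maldanidae sp. (MB)	MB		reassignment	FALSE	0	1
Maldane sarsi	Praxillella sp. (MB)	MB		reassignment	FALSE	0	1
Aglaophamus trissophyllus	Aglaophamus cf. trissophyllus (MB1a-c)	MB1	a-c	retained	TRUE	6	8
Aglaophamus trissophyllus	Aglaophamus sp. (MB2)	MB2		cryptic_split	TRUE	3	22
Aglaophamus trissophyllus	Aglaophamus sp. (MB3)	MB3		cryptic_split	TRUE	2	NA
Aglaophamus trissophyllus	Aglaophamus sp. (MB4)	MB4		reassignment	FALSE	0	1
Aricidea simplex	Aricidea simplex (MB)	MB		retained	FALSE	0	9
Aricidea simplex	Aricidea cf. belgicae (MB1)	MB1		reassignment	TRUE	0	10
Aricidea simplex	Aricidea cf. belgicae (MB2)	MB2		cryptic_split	TRUE	0	2
Aricidea simplex	Aricidea cf. belgicae (MB3)	MB3		cryptic_split	TRUE	0	1
Aricidea simplex	Aricidea cf. pulchra (MB)	MB		reassignment	FALSE	0	1
Harmothoe fuligineum	Harmothoe fuligineum (MB)	MB		retained	FALSE	6	15
Macellicephala sp. A	Macellicephala sp. (MB1)	MB1		retained	TRUE	3	9
Macellicephala sp. A	Macellicephala sp. (MB2)	MB2		cryptic_split	TRUE	1	3
Macellicephaloides sp. B	Macellicephaloides sp. (MB1a-b)	MB1	a-b	retained	FALSE	0	14
Scalibregma inflatum	Scalibregma sp. (MB1)	MB1		retained	TRUE	6	14
Scalibregma inflatum	Scalibregma sp. (MB2)	MB2		cryptic_split	TRUE	1	1
Scalibregma inflatum	Scalibregma sp. (MB3)	MB3		cryptic_split	TRUE	3	4
Laonice weddellia	Laonice weddellia (MB)	MB		retained	FALSE	7	23
Laonice weddellia	Laonice cf. antarctica (MB)	MB		reassignment	FALSE	2	6
Laonice weddellia	Laonice cf. vieitezi (MB)	MB		reassignment	FALSE	0	5
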