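gene_id	subcategory	ts_score	source
CLEC3A	tissue_enhanced	4.7	published
DHRS2	group_enriched	4.4	published
HOXA1	tissue_enhanced	4	published
PADI3	group_enriched	3.4	published
DUOXA2	tissue_enhanced	3.4	published
BMP3	tissue_enhanced	2.6	published
TRPA1	tissue_enhanced	2.4	published
HPGD	tissue_enhanced	NA	published
RBFOX3	group_enriched	NA	published
ACER2	tissue_enhanced	NA	published
CCR8	tissue_enhanced	NA	published
CYP1A1	group_enriched	NA	published
PTGS2	tissue_enhanced	NA	published
OSTN	tissue_enhanced	NA	published
UPK1B	tissue_enhanced	NA	published
IL24	group_enriched	NA	published
MYO3B	tissue_enhanced	NA	published
SHH	tissue_enhanced	NA	published
CTHRC1	tissue_enhanced	NA	published
CHRDL2	group_enriched	NA	published
UPK1A	group_enriched	4.3	published
UPK2	tissue_enriched	38.6	published
UPK3A	group_enriched	NA	published
UPK3B	group_enriched	3.6	published
KRT17	tissue_enhanced	2.8	published
PCP4L1	tissue_enhanced	NA	published
ATP1A4	tissue_enhanced	NA	published
SNX31	group_enriched	4.6	published
SERPINB4	group_enriched	4.5	published
CYP24A1	tissue_enhanced	3.3	published
DKK1	tissue_enhanced	3	published
ALG1L	tissue_enhanced	2.7	published
FSTL4	tissue_enhanced	2.4	published
FOXQ1	tissue_enhanced	2.3	published
EDARADD	tissue_enhanced	2.3	published
CXCL5	tissue_enhanced	2.3	published
GREM1	tissue_enhanced	NA	published
SYNGRP001	group_enriched	NA	synthetic
SYNGRP002	group_enriched	NA	synthetic
SYNGRP003	group_enriched	NA	synthetic
SYNGRP004	group_enriched	NA	synthetic
SYNGRP005	group_enriched	NA	synthetic
SYNGRP006	group_enriched	NA	synthetic
SYNGRP007	group_enriched	NA	synthetic
SYNGRP008	group_enriched	NA	synthetic
SYNGRP009	group_enriched	NA	synthetic
SYNGRP010	group_enriched	NA	synthetic
SYNGRP011	group_enriched	NA	synthetic
SYNGRP012	group_enriched	NA	synthetic
SYNENH001	tissue_enhanced	NA	synthetic
SYNENH002	tissue_enhanced	NA	synthetic
SYNENH003	tissue_enhanced	NA	synthetic
SYNENH004	tissue_enhanced	NA	synthetic
SYNENH005	tissue_enhanced	NA	synthetic
SYNENH006	tissue_enhanced	NA	synthetic
SYNENH007	tissue_enhanced	NA	synthetic
SYNENH008	tissue_enhanced	NA	synthetic
SYNENH009	tissue_enhanced	NA	synthetic
SYNENH010	tissue_enhanced	NA	synthetic
SYNENH011	tissue_enhanced	NA	synthetic
SYNENH012	tissue_enhanced	NA	synthetic
SYNENH013	tissue_enhanced	NA	synthetic
SYNENH014	tissue_enhanced	NA	synthetic
SYNENH015	tissue_enhanced	NA	synthetic
SYNENH016	tissue_enhanced	NA	synthetic
SYNENH017	tissue_enhanced	NA	synthetic
SYNENH018	tissue_enhanced	NA	synthetic
SYNENH019	tissue_enhanced	NA	synthetic
SYNENH020	tissue_enhanced	NA	synthetic
SYNENH021	tissue_enhanced	NA	synthetic
SYNENH022	tissue_enhanced	NA	synthetic
SYNENH023	tissue_enhanced	NA	synthetic
SYNENH024	tissue_enhanced	NA	synthetic
SYNENH025	tissue_enhanced	NA	synthetic
SYNENH026	tissue_enhanced	NA	synthetic
SYNENH027	tissue_enhanced	NA	synthetic
SYNENH028	tissue_enhanced	NA	synthetic
SYNENH029	tissue_enhanced	NA	synthetic
SYNENH030	tissue_enhanced	NA	synthetic
SYNENH031	tissue_enhanced	NA	synthetic
SYNENH032	tissue_enhanced	NA	synthetic
SYNENH033	tissue_enhanced	NA	synthetic
SYNENH034	tissue_enhanced	NA	synthetic
SYNENH035	tissue_enhanced	NA	synthetic
SYNENH036	tissue_enhanced	NA	synthetic
SYNENH037	tissue_enhanced	NA	synthetic
SYNENH038	tissue_enhanced	NA	synthetic
SYNENH039	tissue_enhanced	NA	synthetic
SYNENH040	tissue_enhanced	NA	synthetic
SYNENH041	tissue_enhanced	NA	synthetic
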