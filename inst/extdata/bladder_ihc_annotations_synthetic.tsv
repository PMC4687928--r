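gene_id	antibody_id	compartment	fraction_bin	intensity
CLEC3A	AB0001	whole_urothelium	1	2
DHRS2	AB0002	whole_urothelium	1	3
HOXA1	AB0003	whole_urothelium	3	2
PADI3	AB0004	whole_urothelium	2	3
DUOXA2	AB0005	whole_urothelium	2	2
BMP3	AB0006	whole_urothelium	2	2
TRPA1	AB0007	whole_urothelium	2	3
HPGD	AB0008	whole_urothelium	3	2
RBFOX3	AB0009	whole_urothelium	2	3
ACER2	AB0010	whole_urothelium	2	2
CCR8	AB0011	whole_urothelium	3	2
CYP1A1	AB0012	whole_urothelium	2	3
PTGS2	AB0013	whole_urothelium	1	3
OSTN	AB0014	whole_urothelium	3	3
UPK1B	AB0015	whole_urothelium	3	2
IL24	AB0016	whole_urothelium	1	2
MYO3B	AB0017	whole_urothelium	1	2
SHH	AB0018	whole_urothelium	3	2
CTHRC1	AB0019	whole_urothelium	3	3
CHRDL2	AB0020	whole_urothelium	2	2
UPK1A	AB0021	umbrella	1	2
UPK2	AB0022	umbrella	3	1
UPK3A	AB0023	umbrella	1	1
UPK3B	AB0024	umbrella	1	3
KRT17	AB0025	intermediate_basal	3	2
PCP4L1	AB0026	intermediate_basal	2	3
ATP1A4	AB0027	intermediate_basal	3	3
SNX31	AB0028	other	1	3
SERPINB4	AB0029	other	3	3
CYP24A1	AB0030	other	2	2
DKK1	AB0031	other	2	2
ALG1L	AB0032	other	2	2
FSTL4	AB0033	other	3	1
FOXQ1	AB0034	other	2	1
EDARADD	AB0035	other	3	3
CXCL5	AB0036	other	2	3
GREM1	AB0037	other	3	3
SYNGRP005	AB0038	other	3	2
SYNGRP006	AB0039	other	1	3
SYNGRP007	AB0040	other	2	1
SYNGRP008	AB0041	other	3	3
SYNGRP009	AB0042	other	3	3
SYNGRP010	AB0043	other	3	3
SYNGRP011	AB0044	other	1	3
SYNGRP012	AB0045	other	3	2
SYNENH015	AB0046	other	1	2
SYNENH016	AB0047	other	1	3
SYNENH017	AB0048	other	2	1
SYNENH018	AB0049	other	1	2
SYNENH019	AB0050	other	2	3
SYNENH020	AB0051	other	3	3
SYNENH021	AB0052	other	3	3
SYNENH022	AB0053	other	3	3
SYNENH023	AB0054	other	2	2
SYNENH024	AB0055	other	3	1
SYNENH025	AB0056	other	2	1
SYNENH026	AB0057	other	2	2
SYNENH027	AB0058	other	3	3
SYNENH028	AB0059	other	3	1
SYNENH029	AB0060	other	2	3
SYNENH030	AB0061	other	2	3
SYNENH031	AB0062	other	1	1
SYNENH032	AB0063	other	2	1
SYNENH033	AB0064	other	2	3
SYNENH034	AB0065	other	2	1
SYNENH035	AB0066	other	3	2
SYNENH036	AB0067	other	3	3
SYNENH037	AB0068	other	2	3
SYNENH038	AB0069	other	2	2
SYNENH039	AB0070	other	3	2
SYNENH040	AB0071	other	3	3
SYNENH041	AB0072	other	3	3
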