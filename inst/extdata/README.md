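# Packaged fixtures

`bladder_elevated_genes_synthetic.tsv` — the 90 genes elevated in urinary
bladder (1 tissue enriched, 23 group enriched, 66 tissue enhanced).
Rows with `source = published` carry real gene symbols and, where printed,
TS scores from published immunohistochemical and transcriptomic profiling
of the urinary bladder; the full 90-gene elevated list is only distributed
as supplementary spreadsheets, so the remaining rows
(`source = synthetic`, ids `SYNGRP…` / `SYNENH…`) are synthetic fillers
that keep the subcategory totals at 1/23/66.

`bladder_ihc_annotations_synthetic.tsv` — one consensus IHC annotation per
analyzed elevated gene (72 rows; the 18 missing genes are the
not-yet-analyzed set). Compartments of the 27 localized genes
(20 whole urothelium, 4 umbrella, 3 intermediate/basal) follow the
published captions; the remaining analyzed genes are recorded as `other`.
Antibody ids and the fraction/intensity scores are synthetic.

Load with `read_ihc_annotations()` and `readr::read_tsv()`; see
`compartment_counts()` and `concordance_report()`.
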