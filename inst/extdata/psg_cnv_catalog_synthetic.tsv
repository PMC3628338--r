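# Synthetic stand-in catalog of CNV regions at the human PSG locus (chr19).
# Region identifiers, lengths, overlapped-gene lists and the population
# frequencies of CNVR7655.1/7656.1/7657.1/3825.1 follow published values;
# genomic coordinates and the remaining frequencies are plausible synthetic
# choices (see the package vignette). Columns:
# chrom  start  end  cnv_id  cnv_type  pop:freq[,pop:freq...]  genes
chr19	47610000	47989000	CNVR3824.1	both	CEU:0.10,YRI:0.10,ASN:0.10	PSG1,PSG2,PSG6,PSG7,PSG10,PSG11
chr19	47600000	47838000	CNVR7658.2	loss	CEU:0.10,YRI:0.10,ASN:0.10	PSG1,PSG6,PSG7,PSG10,PSG11
chr19	47990000	48242000	CNVR7658.5	gain	CEU:0.10,YRI:0.10,ASN:0.10	PSG2,PSG4,PSG5,PSG9
chr19	47620000	47655000	CNVR7655.1	gain	CEU:0.05,YRI:0.0	.
chr19	47660000	47690000	CNVR7656.1	loss	CEU:0.05,YRI:0.0	.
chr19	47700000	47760000	CNVR7657.1	gain	YRI:0.15,CEU:0.0	.
chr19	48100000	48150000	CNVR3825.1	gain	ASN:0.80,CEU:0.0,YRI:0.0	PSG4
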