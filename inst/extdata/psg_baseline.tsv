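gene_id	copies
PSG1	2
PSG2	2
PSG3	2
PSG4	2
PSG5	2
PSG6	2
PSG7	2
PSG8	2
PSG9	2
PSG10	2
PSG11	2
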