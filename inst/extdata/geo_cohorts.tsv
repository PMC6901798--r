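cohort	n_tumor	n_normal
GSE32861	59	59
GSE32866	28	27
GSE62948	28	28
GSE63384	35	35
GSE83845	39	0
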