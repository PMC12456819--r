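id	genotype	phenotype
RD01	rd10/rd10	affected
RD02	rd10/rd10	affected
RD03	rd10/rd10	affected
RD04	rd10/rd10	affected
RD05	rd10/rd10	affected
RD06	rd10/rd10	affected
RD07	rd10/rd10	affected
RD08	rd10/rd10	affected
RD09	rd10/+	unaffected
RD10	rd10/+	unaffected
RD11	rd10/+	unaffected
RD12	rd10/+	unaffected
RD13	rd10/+	unaffected
RD14	rd10/+	unaffected
RD15	rd10/+	unaffected
RD16	rd10/+	unaffected
RD17	rd10/+	unaffected
RD18	rd10/+	unaffected
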