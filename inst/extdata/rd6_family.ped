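RD6	294	0	0	1	2	1
RD6	367	0	0	2	1	1
RD6	407	294	367	1	1	1
RD6	408	294	367	1	2	1
RD6	409	294	367	1	2	1
RD6	410	294	367	1	2	1
RD6	411	294	367	1	2	1
RD6	412	294	367	1	1	1
RD6	381	294	367	2	2	1
RD6	382	294	367	2	1	1
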