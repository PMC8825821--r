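batch	channel	sample_label	is_control
batch1	ch01	S1	FALSE
batch1	ch02	S2	FALSE
batch1	ch03	S3	FALSE
batch1	ch04	CONTROL	TRUE
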