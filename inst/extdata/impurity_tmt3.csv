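channel,ch126,ch127,ch128
ch126,0.918,0.079,0.003
ch127,0.040,0.920,0.040
ch128,0.003,0.079,0.918
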