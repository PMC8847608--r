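,body,face,not
body,5601,40,780
face,124,778,88
not,486,54,59517
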