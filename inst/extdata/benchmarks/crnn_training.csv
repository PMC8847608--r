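,body,face,not
body,102038,1297,1653
face,171,14688,63
not,960,311,103717
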