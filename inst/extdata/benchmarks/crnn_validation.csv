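,body,face,not
body,5272,145,1004
face,147,707,136
not,815,129,59113
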