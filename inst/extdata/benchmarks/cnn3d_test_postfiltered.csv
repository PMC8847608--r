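,body,face,not
body,21622,137,1757
face,493,3268,261
not,2328,507,139842
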