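,body,face,not
body,100500,913,3575
face,732,13484,706
not,991,202,103795
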