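s1	lowland
s2	lowland
s3	lowland
s4	lowland
s5	lowland
s6	highland
s7	highland
s8	highland
s9	highland
s10	highland
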