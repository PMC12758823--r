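rule,X1,X2,X3,label
R1,Medium,High,High,1
R2,High,Low,Low,2
R3,Low,Medium,High,1
R4,Low,High,Medium,1
R5,High,Low,Medium,2
R6,Medium,Low,Low,2
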