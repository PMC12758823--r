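rule,Outlook,Temperature,Humidity,Windy,label
R1,Sunny,Hot,High,FALSE,No
R2,Sunny,Hot,High,TRUE,No
R3,Overcast,Hot,High,FALSE,Yes
R4,Rainy,Mild,High,FALSE,Yes
R5,Rainy,Cool,Normal,FALSE,Yes
R6,Rainy,Cool,Normal,TRUE,No
R7,Overcast,Cool,Normal,TRUE,Yes
R8,Sunny,Mild,High,FALSE,No
R9,Sunny,Cool,Normal,FALSE,Yes
R10,Rainy,Mild,Normal,FALSE,Yes
R11,Sunny,Mild,Normal,TRUE,Yes
R12,Overcast,Mild,High,TRUE,Yes
R13,Overcast,Hot,Normal,TRUE,Yes
R14,Rainy,Mild,High,TRUE,No
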