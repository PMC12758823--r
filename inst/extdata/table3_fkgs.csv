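rule,Outlook,Temperature,Humidity,Windy,label
R3,Overcast,Hot,High,FALSE,Yes
R6,Rainy,Cool,Normal,TRUE,No
R8,Sunny,Mild,High,FALSE,No
R9,Sunny,Cool,Normal,FALSE,Yes
R11,Sunny,Mild,Normal,TRUE,Yes
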