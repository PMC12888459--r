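peak_id,betweenness,closeness,degree,source,flagged
A1,0.0155,0.3625,4,GF,FALSE
A6,0.0331,0.3718,3,SR,FALSE
A7,0.0535,0.3816,3,SR,TRUE
A9,0.0361,0.3718,2,SR,FALSE
A11,0.0321,0.3816,5,GF,TRUE
A17,0.0082,0.3625,2,SR,FALSE
A18,0.0478,0.4028,4,GF,TRUE
A19,0.0213,0.3816,3,SR,FALSE
A20,0.0213,0.3816,3,SR,FALSE
A24,0.0082,0.3625,2,SR,FALSE
A26,0.0082,0.3625,2,SR,FALSE
A27,0.1878,0.4531,5,GF,TRUE
A30,0.0082,0.3625,2,SR,FALSE
A32,0.0478,0.4028,4,SR,TRUE
A34,0.0082,0.3625,2,GF,FALSE
A40,0.0305,0.3816,2,GF,TRUE
B11,0.0611,0.3816,2,GF,TRUE
B14,0.0081,0.3537,2,GF,FALSE
B16,0.0321,0.3816,5,GF,TRUE
B17,0.0155,0.3625,4,GF,FALSE
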