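peak_id,herb,herb_alt
A1,GF,GF
A2,GF,GF
A3,GF,GF
A4,GF,GF
A5,GF,GF
A6,GF,SR
A7,GF,SR
A8,GF,GF
A9,GF,SR
A10,GF,GF
A11,GF,GF
A12,GF,GF
A13,GF,GF
A14,SR,SR
A15,SR,SR
A16,SR,SR
A17,SR,SR
A18,SR,GF
A19,SR,SR
A20,SR,SR
A21,SR,SR
A22,SR,SR
A23,GF,GF
A24,SR,SR
A25,SR,SR
A26,SR,SR
A27,SR,GF
A28,SR,SR
A29,SR,SR
A30,SR,SR
A31,SR,SR
A32,SR,SR
A33,SR,SR
A34,SR,GF
A35,SR,SR
A36,SR,SR
A37,SR,SR
A38,SR,SR
A39,SR,SR
A40,GF,GF
B1,GF,GF
B2,GF,GF
B3,GF,GF
B4,GF,GF
B5,GF,GF
B6,GF,GF
B7,GF,GF
B8,GF,GF
B9,GF,GF
B10,GF,GF
B11,GF,GF
B12,GF,GF
B13,GF,GF
B14,GF,GF
B15,GF,GF
B16,GF,GF
B17,GF,GF
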