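indicator,peaks
Lung injury score,A40;A27;A11;B14;B16
TNF-a,A7;A32;A18;A6
IL-6,A27;B16;A11;A1;B17;A6
IL-1b,A20;A18;A19;A32;A7
W/D ratio of Lung,B16;A11;A27;A1;B17
Protein in BALF,A9;A20;A19;A18;A32
Neutrophils in BALF,A24;A26;A30;A34;A17;B11
Overall rating,A11;B16;A27;A1;B17
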