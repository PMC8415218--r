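id,dose_mg,time_h,conc_norm_atrl,conc_norm_met,p_adherent_atrl,p_partial_atrl,p_nonadherent_atrl,p_adherent_met,p_partial_met,p_nonadherent_met,reported_call
A1,40,12,0.312,0.775,0.7974,0.0362,0.0003,0.9529,0.2567,0.0265,PA
A2,20,16,0.312,0.782,0.7159,0.0231,0.0030,0.7848,0.1904,0.0244,A
A3,20,12,0.064,0.174,0.9769,0.2954,0.0113,0.9998,0.6482,0.0987,PA
A4,20,16,1.032,2.474,0.1359,0.0033,0.0000,0.3369,0.0345,0.0103,A
A5,40,16,0.015,0.117,0.9684,0.5972,0.0179,0.9779,0.6384,0.1157,PA
A6,20,15,0.497,1.081,0.6103,0.0147,0.0020,0.7518,0.1375,0.0197,A
A7,20,16,0.492,1.393,0.5538,0.0133,0.0020,0.7014,0.0879,0.0160,A
A8,20,15,0.323,1.253,0.7345,0.0249,0.0030,0.7384,0.1115,0.0174,A
A9,20,16,0.145,0.538,0.7840,0.0563,0.0061,0.8994,0.2815,0.0336,PA
A10,20,16,0.378,0.960,0.6644,0.0186,0.0028,0.7536,0.1493,0.0208,A
A11,20,18,0.222,0.926,0.7219,0.0275,0.0042,0.7361,0.1356,0.0206,A
A12,40,2,0.274,0.572,1.0000,0.2180,0.0056,1.0000,0.6319,0.0487,PA
A13,20,13,0.533,1.098,0.6872,0.0163,0.0019,0.7800,0.1548,0.0200,A
A14,40,12,0.223,0.367,0.8357,0.0556,0.0049,0.9840,0.4595,0.0533,PA
A15,80,20,0.567,0.952,0.2433,0.0088,0.0012,0.6863,0.1155,0.0196,A
A16,20,10,0.294,0.623,0.8772,0.0515,0.0042,0.9898,0.3603,0.0349,PA
A17,10,18,0.364,0.973,0.5753,0.0161,0.0028,0.7297,0.1283,0.0200,A
A18,40,12,0.533,2.176,0.7233,0.0187,0.0020,0.6712,0.0581,0.0116,A
A19,20,12,0.734,1.679,0.6147,0.0121,0.0009,0.7419,0.0887,0.0144,A
A20,20,14,0.227,0.670,0.7857,0.0418,0.0046,0.9140,0.2596,0.0289,PA
A21,20,12,0.154,0.398,0.8912,0.0904,0.0065,0.9820,0.4384,0.0495,PA
A22,20,12,0.617,1.722,0.6886,0.0149,0.0015,0.7384,0.0849,0.0142,A
A23,20,2,1.562,3.560,0.8474,0.0126,0.0002,0.7348,0.0560,0.0095,A
A24,20,2,0.949,2.351,0.9451,0.0329,0.0010,0.9320,0.1261,0.0129,PA
A25,80,15,0.850,1.778,0.3580,0.0082,0.0006,0.6357,0.0653,0.0129,A
A26,20,12,0.700,1.727,0.6375,0.0126,0.0011,0.7382,0.0846,0.0141,A
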