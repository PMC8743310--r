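gene,S1,S2,S3,S4,S5,S6,S7,S8,S9,S10,S11,S12,S13,S14,S15,S16,S17,S18
Mk,8.56302,9.38716,8.79905,8.89243,9.30263,8.69272,8.63779,8.87153,8.80396,3.65665,4.43792,3.75947,4.03418,4.06851,3.07062,4.17314,4.75082,3.99313
Cp,8.61238,9.65558,9.13026,9.50701,9.1078,9.3067,9.72299,9.32904,9.18762,3.66266,4.29024,3.79289,5.09025,4.17143,3.60099,4.82052,3.77,3.20676
Gr,3.47754,4.31494,4.37222,5.11165,5.06179,4.54211,5.61987,6.94239,6.1316,6.35263,6.88088,8.06182,7.09373,8.21386,7.81071,8.24797,8.52827,9.39047
G0001,4.52059,3.52621,3.19528,4.05815,4.59349,5.41814,3.35519,3.70879,5.34702,5.50892,2.04149,4.36943,2.83079,5.17093,3.45585,3.89974,5.15828,4.50038
G0002,2.92031,3.59179,4.68975,4.64533,3.10822,4.71179,3.76858,2.2656,3.15297,2.8445,5.47359,5.21627,2.94799,6.28873,3.83459,2.9066,3.09089,4.57691
G0003,4.13924,3.26957,3.67133,5.72563,4.57725,3.5975,2.76363,3.72727,4.4434,2.44319,3.52512,3.50616,2.52815,2.93114,4.55217,4.50325,4.33499,5.14269
G0004,3.91525,3.77856,3.83532,3.47103,3.17509,4.79936,3.03904,2.20007,3.02285,3.94475,4.98117,3.77222,2.80656,5.9062,5.03333,4.94924,4.77585,3.29255
G0005,3.33336,3.77418,2.60797,4.16639,2.84275,4.42648,4.13396,5.15274,6.12449,4.84919,2.17564,2.88835,3.65202,6.1318,3.95382,4.3828,4.23714,3.38144
G0006,1.48391,1.45312,5.46582,3.74528,4.778,2.8301,3.00095,2.99668,4.6877,3.9889,3.73939,4.99583,4.53282,4.23146,6.63871,4.37158,2.44013,3.99169
G0007,3.26485,5.347,4.04821,4.33278,2.79578,3.7938,3.85853,4.14821,3.65663,3.23969,3.04115,4.56183,3.28901,4.89695,4.58901,4.15722,4.02433,4.33892
G0008,2.97988,4.61641,5.90808,4.18243,4.30671,3.06939,4.16733,4.5195,4.78517,5.1758,3.5097,2.43572,3.80101,2.26121,3.79762,4.84794,4.33464,5.40541
G0009,4.11355,4.21756,5.73094,5.16459,3.16634,4.4494,3.80121,4.00544,2.84442,6.41445,2.9227,5.48108,3.71863,4.46885,4.44156,2.71661,4.98941,3.13473
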