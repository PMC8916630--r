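birth_year,sex,age,q
1930,M,60,0.011828
1930,M,61,0.012858
1930,M,62,0.013978
1930,M,63,0.015196
1930,M,64,0.016519
1930,M,65,0.017958
1930,M,66,0.019522
1930,M,67,0.021222
1930,M,68,0.023071
1930,M,69,0.02508
1930,M,70,0.027264
1930,M,71,0.029639
1930,M,72,0.032221
1930,M,73,0.035027
1930,M,74,0.038078
1930,M,75,0.041394
1930,M,76,0.045
1930,M,77,0.048919
1930,M,78,0.05318
1930,M,79,0.057812
1930,M,80,0.062847
1940,M,60,0.011
1940,M,61,0.011958
1940,M,62,0.013
1940,M,63,0.014132
1940,M,64,0.015363
1940,M,65,0.016701
1940,M,66,0.018155
1940,M,67,0.019737
1940,M,68,0.021456
1940,M,69,0.023324
1940,M,70,0.025356
1940,M,71,0.027564
1940,M,72,0.029965
1940,M,73,0.032575
1940,M,74,0.035412
1940,M,75,0.038497
1940,M,76,0.04185
1940,M,77,0.045495
1940,M,78,0.049457
1940,M,79,0.053765
1940,M,80,0.058448
1950,M,60,0.01023
1950,M,61,0.011121
1950,M,62,0.01209
1950,M,63,0.013143
1950,M,64,0.014287
1950,M,65,0.015532
1950,M,66,0.016884
1950,M,67,0.018355
1950,M,68,0.019954
1950,M,69,0.021692
1950,M,70,0.023581
1950,M,71,0.025635
1950,M,72,0.027868
1950,M,73,0.030295
1950,M,74,0.032933
1950,M,75,0.035802
1950,M,76,0.03892
1950,M,77,0.04231
1950,M,78,0.045995
1950,M,79,0.050001
1950,M,80,0.054356
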