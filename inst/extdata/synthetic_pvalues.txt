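# synthetic p-values: 30 drawn from Beta(0.3, 4) (enriched near 0),
# 70 from Uniform(0, 1); generated with a fixed seed for the examples
0.196003
0.056923
0.138838
0.163670
0.216777
0.028410
0.000017
0.034484
0.047563
0.289250
0.008302
0.009484
0.071475
0.025273
0.008937
0.021838
0.008573
0.000000
0.003208
0.002597
0.000241
0.000004
0.095768
0.007297
0.069173
0.000622
0.000157
0.084678
0.039715
0.000756
0.499060
0.964025
0.141486
0.775984
0.494406
0.823093
0.775180
0.139950
0.384284
0.309291
0.798161
0.944869
0.569395
0.321708
0.846706
0.842765
0.342895
0.704121
0.744001
0.484862
0.311108
0.590655
0.954753
0.899523
0.328888
0.669063
0.533098
0.999047
0.046281
0.595092
0.430967
0.855988
0.234486
0.330973
0.856541
0.160192
0.133900
0.436042
0.606873
0.318351
0.247437
0.811596
0.634958
0.420967
0.127586
0.331794
0.496412
0.855136
0.432903
0.683825
0.667786
0.222994
0.158039
0.213670
0.075873
0.936904
0.887732
0.742044
0.476352
0.202683
0.625018
0.678964
0.372378
0.147618
0.708896
0.311676
0.578189
0.225806
0.520185
0.087469
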