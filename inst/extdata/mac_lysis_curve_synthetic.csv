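"mac_per_cell","percent","provenance"
0.1,4.71092210386216,"synthetic look-alike; generated from the fitted sigmoid, seed 42"
0.144523016930896,2.36471313576175,"synthetic look-alike; generated from the fitted sigmoid, seed 42"
0.208869024228082,6.85292220614729,"synthetic look-alike; generated from the fitted sigmoid, seed 42"
0.301863815248548,11.7920425607485,"synthetic look-alike; generated from the fitted sigmoid, seed 42"
0.436262692819909,18.3050887718942,"synthetic look-alike; generated from the fitted sigmoid, seed 42"
0.630500005407302,27.4434173450623,"synthetic look-alike; generated from the fitted sigmoid, seed 42"
0.911217629564097,43.8197282700633,"synthetic look-alike; generated from the fitted sigmoid, seed 42"
1.31691920905223,55.2108617850986,"synthetic look-alike; generated from the fitted sigmoid, seed 42"
1.90325137146478,73.1642612410843,"synthetic look-alike; generated from the fitted sigmoid, seed 42"
2.75063630181957,80.0184720545943,"synthetic look-alike; generated from the fitted sigmoid, seed 42"
3.97530256818607,90.5261931841845,"synthetic look-alike; generated from the fitted sigmoid, seed 42"
5.74522720367391,97.488730534598,"synthetic look-alike; generated from the fitted sigmoid, seed 42"
8.30317568428412,93.1640768333535,"synthetic look-alike; generated from the fitted sigmoid, seed 42"
12,97.1496898036744,"synthetic look-alike; generated from the fitted sigmoid, seed 42"
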