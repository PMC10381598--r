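site	n_sh	n_otus
Brigham Young University	65	94
Broom Canyon	146	171
Moores Creek	98	125
Mosquito Creek	115	145
Paul Bunyans Woodpile	144	188
Pine Creek	112	135
Death Hollow	100	121
Delano Peak	123	159
Harmon Creek	80	103
Quail Creek	103	122
Whipple Creek	96	123
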