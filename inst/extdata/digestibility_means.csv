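rapeseed_oil,CP,sum_FA,14:0,16:0,18:0,20:0,16:1n7,18:1n9,20:1,22:1n9,18:2n6,20:4n6,18:3n3,20:5n3,22:5n3,22:6n3
0,86.8,81.0,75.0,60.5,41.5,52.5,96.5,93.0,89.5,80.0,89.0,97.0,90.0,98.0,97.0,96.0
5,86.2,81.0,73.0,58.5,37.5,50.5,95.0,93.5,88.0,81.5,92.5,96.5,94.5,97.5,95.0,95.0
9,88.1,87.5,81.0,68.5,47.0,56.0,98.0,97.0,94.0,89.0,96.0,98.5,97.0,99.0,97.5,97.0
14,86.1,89.0,82.0,70.5,48.0,56.5,98.0,97.0,93.5,91.0,96.0,98.0,97.5,99.0,97.5,97.0
19,87.8,92.0,87.5,79.0,57.0,64.0,98.5,98.0,95.5,94.0,97.0,98.0,98.0,99.0,97.5,97.0
24,86.6,94.0,91.0,85.0,63.5,70.0,98.5,98.0,95.5,95.5,97.0,97.5,98.5,99.0,96.5,96.5
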