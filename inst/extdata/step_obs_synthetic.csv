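# source: synthetic; coherent_ffl at answer parameters, step input, N(0,0.01) noise, seed 101
"time","value"
1,0.21452576646079
2,0.587547591717053
3,0.609429375459096
4,0.763066604578928
5,0.800404480491405
6,0.898302812895183
7,0.847550288066115
8,0.776336103853911
9,0.880093446700367
10,0.766377044682441
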