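# source: synthetic; coherent_ffl at answer parameters, pulse input (off at t=5), N(0,0.01) noise, seed 102
"time","value"
1,0.265181705694296
2,0.610774810185365
3,0.541607302475961
4,0.939960479300576
5,0.89317472920932
6,0.403563902557272
7,0.193909605704567
8,0.0637368210340305
9,0.0690747756583213
10,0.195529628344003
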