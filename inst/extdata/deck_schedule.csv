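deck,block,reward,loss,loss_probability
A,1,100,-250,0.5
B,1,100,-1250,0.1
C,1,50,-50,0.5
D,1,50,-250,0.1
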