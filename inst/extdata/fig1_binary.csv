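id,parent_id,length,alpha_up,alpha_down
1,,1,,
2,1,0.8,0.5,0.5
3,1,0.9,0.7,0.7
4,2,0.6,0.5,0.5
5,2,0.7,0.9,0.9
6,3,1,0.4,0.4
7,3,0.5,0.8,0.8
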