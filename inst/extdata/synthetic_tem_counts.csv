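time_h,species,length,count
0.5,cylinder,1,120
0.5,cylinder,2,64
0.5,cylinder,3,38
0.5,cylinder,5,12
0.5,cylinder,9,3
18,cylinder,1,180
18,cylinder,2,14
18,cylinder,3,4
18,cuboid,1,70
18,cuboid,2,48
18,cuboid,3,31
18,cuboid,5,16
18,cuboid,8,6
18,cuboid,14,1
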