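domain 1 9
domain 10 7
domain 2 16
domain 5 8
domain 6 8
domain 6 8 mismatch=4
domain 7 16
domain 8 16 bridge
domain 9 16 bridge
strand c1 1 2 5 labels=Cy5
strand c1s 9
strand c2 6' 7 labels=Cy3
strand c2s 8
strand input 9* 2* 5*
strand activator 2* 6* 7* 8* 10 labels=quencher hairpin=6*,7*,8*|2*|while_guard_bound|6*
strand inhibitor 7* 1* 2* 5* labels=quencher hairpin=1*,2*,5*|7*|while_guard_bound|1*
strand fuelA 10* 7* 8*
strand fuelB 10* 7*
strand threshold 6 7 hairpin=7|6|until_guard_bound|
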