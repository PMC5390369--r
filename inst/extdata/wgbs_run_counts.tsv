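sample	total_reads	mapped_reads	mc_cg	mc_chg	mc_chh
CK	349288166	228002142	47879971	45874296	107789421
D	379630307	256948717	50588873	48445561	133842065
Re_W	376067028	253873809	49367000	47336957	118994955
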