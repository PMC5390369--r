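category	n_changed	n_total
all_demethylated	46	65
ethylene	4	6
gibberellin	5	9
cytokinin	7	16
auxin	14	34
expression_changed	54	65
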