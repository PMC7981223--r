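year,group,n_nests
2005,resident,17
2007,resident,27
2017,translocated,8
2018,translocated,9
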