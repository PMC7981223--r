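year,season,n_females,n_chicks
2017,spring,40,0
2018,spring,20,0
2018,brood,6,26
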