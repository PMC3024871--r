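rs01	6	31478000
rs02	6	31482000
rs03	6	31486000
rs04	6	31490000
rs05	6	31494000
rs06	6	31498000
rs07	6	31502000
rs08	6	31506000
rs09	6	31510000
rs10	6	31514000
rs11	6	31518000
rs12	6	31522000
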