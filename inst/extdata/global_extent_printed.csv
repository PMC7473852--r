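quantity,km2
total_1996,141945
total_2016,135870
maximal_extent,145595
carbonate_extent,14657
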