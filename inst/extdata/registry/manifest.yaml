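# Dataset manifest: per-subfamily sequence counts of the 268-sequence
# GH13 alpha-amylase study set, split by taxon domain.
GH13_1:  {procarya: 2,  eucarya: 37}
GH13_5:  {procarya: 32, eucarya: 3}
GH13_15: {procarya: 0,  eucarya: 28}
GH13_24: {procarya: 0,  eucarya: 23}
GH13_32: {procarya: 20, eucarya: 120}
GH13_42: {procarya: 2,  eucarya: 1}
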