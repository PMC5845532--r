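model	neg2ll	df
I	1937.52	746
II	1937.56	747
III	1946.97	748
IV	1954.68	749
V	1947.63	751
VI	1947.63	750
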