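taxon,allergenicity
Alnus,high
Ambrosia,high
Artemisia,high
Betula,high
Carpinus,moderate
Castanea,low
Chenopodiaceae,moderate
Corylus,high
Cupressaceae/Taxaceae,moderate
Ericaceae,low
Fagus,moderate
Fraxinus,high
Pinus,low
Plantago,moderate
Platanus,moderate
Poaceae,high
Populus,low
Quercus,moderate
Rumex,moderate
Salix,moderate
Tilia,low
Ulmus,moderate
Urticaceae,moderate
Total,low
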