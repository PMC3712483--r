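# Canonical 24-individual RAD panel order.
individual_id	role	phenotype_class
father	father	pink-unbanded
mother	mother	yellow-banded
PB01	offspring	pink-banded
PB02	offspring	pink-banded
PB03	offspring	pink-banded
PB04	offspring	pink-banded
PB05	offspring	pink-banded
PB06	offspring	pink-banded
PB07	offspring	pink-banded
PB08	offspring	pink-banded
PB09	offspring	pink-banded
PB10	offspring	pink-banded
PB11	offspring	pink-banded
PB12	offspring	pink-banded
YU01	offspring	yellow-unbanded
YU02	offspring	yellow-unbanded
YU03	offspring	yellow-unbanded
YU04	offspring	yellow-unbanded
YU05	offspring	yellow-unbanded
YU06	offspring	yellow-unbanded
YU07	offspring	yellow-unbanded
YU08	offspring	yellow-unbanded
YU09	offspring	yellow-unbanded
YU10	offspring	yellow-unbanded
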