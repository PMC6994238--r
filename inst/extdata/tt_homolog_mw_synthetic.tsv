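protein_id	species	homolog_id	homolog_mw_kda
FAP115	T. thermophila	TTHERM_00193760	78
FAP106	T. thermophila	TTHERM_00137550	28
FAP252	T. thermophila	TTHERM_00899430	41
FAP161	T. thermophila	TTHERM_00155380	112
FAP77	T. thermophila	TTHERM_00974270	31
FAP71	T. thermophila	TTHERM_00077710	34
EEF1	T. thermophila	TTHERM_00655820	52
FAP182	T. thermophila	TTHERM_01049330	50
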