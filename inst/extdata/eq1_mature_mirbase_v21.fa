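>hsa-miR-199a-3p MIMAT0000232 Homo sapiens miR-199a-3p
ACAGUAGUCUGCACAUUGGUUA
>hsa-miR-941 MIMAT0004984 Homo sapiens miR-941
CACCCGGCUGUGUGCACAUGUGC
>hsa-miR-103a-3p MIMAT0000101 Homo sapiens miR-103a-3p
AGCAGCAUUGUACAGGGCUAUGA
>hsa-miR-92a-3p MIMAT0000092 Homo sapiens miR-92a-3p
UAUUGCACUUGUCCCGGCCUGU
>hsa-miR-31-5p MIMAT0000089 Homo sapiens miR-31-5p
AGGCAAGAUGCUGGCAUAGCU
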