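type	fusion_site_5	fusion_site_3
1	CCCT	AACG
2	AACG	TATG
3	TATG	ATCC
3a	TATG	TTCT
3b	TTCT	ATCC
4	ATCC	GCTG
4a	ATCC	TGGC
4b	TGGC	GCTG
5	GCTG	TACA
6	TACA	GAGT
7	GAGT	CCGA
8	CCGA	CCCT
8a	CCGA	CAAT
8b	CAAT	CCCT
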