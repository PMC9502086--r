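>AAC1_synthetic bovine-AAC1-like synthetic carrier sequence
LTVMSAILLTVMSAILLTVMSAILLTPVDRLKLRAQVQHASKQISAEKQYAGIIDCVVRI
PKEDGSSAVYRGLTVMSAILLTVMSAILLTVMSAILLTVMSAILLTVMSAILLTVMSAIL
LTVMSAILLTVPADFARSRTAADVGKSGTEREFSGLGDCLVKITKSDGLTVMSAILLTVM
SAILLTVMSAILLTVMSAILLTVMSAILLTVMSAILLTVMSAILLTVMPLDTVRRRMMMQ
SGRKGADIMYTGTVDCWRKIARDEGLTVMSAILLTVMSAILLTVMSAILLTVMSAIL
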