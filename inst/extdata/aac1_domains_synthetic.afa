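>domain1/27-65
P----VDRLKLRAQVQHASKQISAEKQYAGIIDCVVRIPKEDG
>domain2/132-168
PADFARSR----TAADVGKS--GTEREFSGLGDCLVKITKSDG
>domain3/229-265
PLDTVRRR----MMMQSGRK--GADIMYTGTVDCWRKIARDEG
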