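,Human,Goat,Opossum,Gallus,Lemur,Mouse,Rabbit,Rat,Gorilla,Bovine,Chimp
Human,0,23.39,26.94,28.34,27.82,23.49,19.31,27.88,4.77,21.6,7.26
Goat,23.39,0,28.71,24.16,25.89,25.52,24.33,27.43,21.77,8.73,24.26
Opossum,26.94,28.71,0,29.55,31.23,29.21,26.69,30.52,26.9,28.16,28.44
Gallus,28.34,24.16,29.55,0,28.66,30.22,26.27,30.89,28.25,26.21,30.51
Lemur,27.82,25.89,31.23,28.66,0,30.21,27.63,30.96,27.77,25.91,30.27
Mouse,23.49,25.52,29.21,30.22,30.21,0,24.09,26.43,20.98,23.17,23.29
Rabbit,19.31,24.33,26.69,26.27,27.63,24.09,0,29.19,19.02,22.28,21.5
Rat,27.88,27.43,30.52,30.89,30.96,26.43,29.19,0,28.37,27.95,30.21
Gorilla,4.77,21.77,26.9,28.25,27.77,20.98,19.02,28.37,0,19.48,9.62
Bovine,21.6,8.73,28.16,26.21,25.91,23.17,22.28,27.95,19.48,0,21.97
Chimp,7.26,24.26,28.44,30.51,30.27,23.29,21.5,30.21,9.62,21.97,0
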