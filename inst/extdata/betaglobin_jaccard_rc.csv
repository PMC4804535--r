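,Human,Goat,Opossum,Gallus,Lemur,Mouse,Rabbit,Rat,Gorilla,Bovine,Chimp
Human,0,0.7,0.82,0.8,0.76,0.7,0.61,0.8,0.15,0.69,0.26
Goat,0.7,0,0.84,0.74,0.74,0.77,0.77,0.79,0.69,0.36,0.71
Opossum,0.82,0.84,0,0.85,0.87,0.91,0.84,0.9,0.82,0.85,0.82
Gallus,0.8,0.74,0.85,0,0.81,0.82,0.79,0.85,0.8,0.81,0.8
Lemur,0.76,0.74,0.87,0.81,0,0.83,0.81,0.81,0.76,0.72,0.77
Mouse,0.7,0.77,0.91,0.82,0.83,0,0.78,0.78,0.64,0.74,0.68
Rabbit,0.61,0.77,0.84,0.79,0.81,0.78,0,0.81,0.63,0.75,0.65
Rat,0.8,0.79,0.9,0.85,0.81,0.78,0.81,0,0.8,0.82,0.82
Gorilla,0.15,0.69,0.82,0.8,0.76,0.64,0.63,0.8,0,0.67,0.15
Bovine,0.69,0.36,0.85,0.81,0.72,0.74,0.75,0.82,0.67,0,0.69
Chimp,0.26,0.71,0.82,0.8,0.77,0.68,0.65,0.82,0.15,0.69,0
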