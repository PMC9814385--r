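# toy reaction corpus (synthetic, seeded); one equation per line
C#C + [N]=O >> C#N + [CH]=O
C=O + [O] >> [OH] + [CH]=O
2N#N + 3OC=O >> O=C=O + 2[CH3] + 4[N]=O
C=C + 4[OH] >> CC=O + 4[H] + 3[O]
NN + [NH2] >> N#N + N + 3[H]
CC=O >> [CH3] + [CH]=O
3C#N + COC >> 3C#N + CCO
C=C + 3[H] >> [H][H] + C=C + [H]
C#C + N + 2[H] >> [H][H] + C#C + N
O + 3O=C=O + 2[O] >> 3O=C=O + [O] + 2[OH]
3[H][H] + COC >> 2[H][H] + CC=O + 4[H]
[H][H] + CC=O + 4[OH] >> 3O + OO + C#C
OO >> [H] + [O]O
2O + OO >> [H][H] + 2OO
2[O] >> O=O
O=C=O + NN >> O=C=O + 2[NH2]
[OH] + [O]O >> O=O + [H] + [OH]
NN + 2[CH]=O >> 2C#N + 3[H] + [O]O
N + [H] >> 2[H] + [NH2]
OO + C#C >> C#C + [H] + [O]O
C=O + 2C#N >> 2C#N + [H] + [CH]=O
3C=O + 2C#N >> 2C#N + [H] + [CH]=O
N + [H] >> 4[H] + [NH2]
3C=C + 4[OH] >> CC=O + 4[H] + 3[O]
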