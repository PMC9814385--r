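canonical_smiles,H_eV,S_eV_per_K,dipole_debye
[H][H],0,0.001,0
O=O,0,0.002,0
O,-2.5,0.0015,1.85
OO,-1.2936032563448,0.00161182639026083,0.772451101569459
C,-2.37209923239425,0.000648406184162013,0.590659143403172
C(=O)=O,1.20634475536644,0.00118787296186201,0.409202714916319
C=O,0.167759905569255,0.000577870648237877,1.87189950747415
CO,1.84761120518669,0.000536205859505571,0.521235849475488
CC,2.7390007507056,0.00171792257239576,2.59930373565294
C=C,-2.33728188788518,0.00198787905753125,2.96800705860369
C#C,-1.36029030242935,0.0019946325920755,2.95990728540346
N#N,-0.0569207891821861,0.00149420128739439,2.67603924963623
N,-1.08957588812336,0.0014920759923989,2.66465283161961
C#N,0.355036959517747,0.00254019017342944,0.472030544187874
CC=O,-1.42444116761908,0.00108799688587897,2.79137841286138
C(O)=O,-1.788748732768,0.00256717561522964,2.48079074034467
NN,-0.674845517612994,0.00183368982875254,2.48803025297821
COC,2.3272186294198,0.00282235678413417,2.15202088630758
CCO,0.329535323660821,0.0018744868140202,0.469078861176968
[H],2.05307631148025,0.00240035631705541,2.50638422160409
[O],2.34124268777668,0.00067127440602053,0.0681738504208624
[OH],1.32420582231134,0.0024840233476134,2.75738127040677
[CH3],-1.73195835761726,0.00208200856938493,0.117056847782806
[O]O,-1.64569625537843,0.00146144234121311,2.10035876068287
[N]=O,-2.16009781742468,0.00191568168764934,1.32989952201024
[NH2],-0.120516875758767,0.00280497641838156,0.94160535489209
[CH]=O,-0.37552884221077,0.00293969403381925,2.81830944679677
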