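# WAG amino-acid exchangeability rates (Whelan & Goldman 2001, Mol Biol Evol 18:691-699).
# Symmetric; one line per unordered pair: aa1 aa2 rate. Diagonal implied zero.
A R 0.551571
A N 0.509848
A D 0.738998
A C 1.02704
A Q 0.908598
A E 1.58285
A G 1.41672
A H 0.316954
A I 0.193335
A L 0.397915
A K 0.906265
A M 0.893496
A F 0.210494
A P 1.43855
A S 3.37079
A T 2.12111
A W 0.113133
A Y 0.240735
A V 2.00601
R N 0.635346
R D 0.147304
R C 0.528191
R Q 3.0355
R E 0.439157
R G 0.584665
R H 2.13715
R I 0.186979
R L 0.497671
R K 5.35142
R M 0.683162
R F 0.102711
R P 0.679489
R S 1.22419
R T 0.554413
R W 1.16392
R Y 0.381533
R V 0.251849
N D 5.42942
N C 0.265256
N Q 1.54364
N E 0.947198
N G 1.12556
N H 3.95629
N I 0.554236
N L 0.131528
N K 3.01201
N M 0.198221
N F 0.0961621
N P 0.195081
N S 3.97423
N T 2.03006
N W 0.0719167
N Y 1.086
N V 0.196246
D C 0.0302949
D Q 0.616783
D E 6.17416
D G 0.865584
D H 0.930676
D I 0.039437
D L 0.0848047
D K 0.479855
D M 0.103754
D F 0.0467304
D P 0.423984
D S 1.07176
D T 0.374866
D W 0.129767
D Y 0.325711
D V 0.152335
C Q 0.0988179
C E 0.021352
C G 0.306674
C H 0.248972
C I 0.170135
C L 0.384287
C K 0.0740339
C M 0.390482
C F 0.39802
C P 0.109404
C S 1.40766
C T 0.512984
C W 0.71707
C Y 0.543833
C V 1.00214
Q E 5.46947
Q G 0.330052
Q H 4.29411
Q I 0.113917
Q L 0.869489
Q K 3.8949
Q M 1.54526
Q F 0.0999208
Q P 0.933372
Q S 1.02887
Q T 0.857928
Q W 0.215737
Q Y 0.22771
Q V 0.301281
E G 0.567717
E H 0.570025
E I 0.127395
E L 0.154263
E K 2.58443
E M 0.315124
E F 0.0811339
E P 0.682355
E S 0.704939
E T 0.822765
E W 0.156557
E Y 0.196303
E V 0.588731
G H 0.24941
G I 0.0304501
G L 0.0613037
G K 0.373558
G M 0.1741
G F 0.049931
G P 0.24357
G S 1.34182
G T 0.225833
G W 0.336983
G Y 0.103604
G V 0.187247
H I 0.13819
H L 0.499462
H K 0.890432
H M 0.404141
H F 0.679371
H P 0.696198
H S 0.740169
H T 0.473307
H W 0.262569
H Y 3.87344
H V 0.118358
I L 3.17097
I K 0.323832
I M 4.25746
I F 1.05947
I P 0.0999288
I S 0.31944
I T 1.45816
I W 0.212483
I Y 0.42017
I V 7.8213
L K 0.257555
L M 4.85402
L F 2.11517
L P 0.415844
L S 0.344739
L T 0.326622
L W 0.665309
L Y 0.398618
L V 1.80034
K M 0.934276
K F 0.088836
K P 0.556896
K S 0.96713
K T 1.38698
K W 0.137505
K Y 0.133264
K V 0.305434
M F 1.19063
M P 0.171329
M S 0.493905
M T 1.51612
M W 0.515706
M Y 0.428437
M V 2.05845
F P 0.161444
F S 0.545931
F T 0.171903
F W 1.52964
F Y 6.45428
F V 0.649892
P S 1.61328
P T 0.795384
P W 0.139405
P Y 0.216046
P V 0.314887
S T 4.37802
S W 0.523742
S Y 0.786993
S V 0.232739
T W 0.110864
T Y 0.291148
T V 1.38823
W Y 2.48539
W V 0.365369
Y V 0.31473
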