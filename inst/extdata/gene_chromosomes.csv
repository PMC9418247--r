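gene,chrom,base_pos
KRAS,12,25205246
TP53,17,7668402
CDKN2A,9,21967752
SMAD4,18,51030213
ATM,11,108222484
BRCA1,17,43044295
BRCA2,13,32315086
PALB2,16,23603160
CHEK2,22,28687743
MLH1,3,36993226
MSH2,2,47403067
MSH6,2,47695530
PMS2,7,5970925
ARID1A,1,26696015
GATA6,18,22169443
RNF43,17,58352500
TGFBR2,3,30606493
MAP2K4,17,12020824
GNAS,20,58839718
MYC,8,127735434
PIK3CA,3,179148114
APC,5,112707498
FBXW7,4,152320544
ERBB2,17,39688094
EGFR,7,55019017
BRAF,7,140719327
CTNNB1,3,41199505
STK11,19,1205778
CDK12,17,39461486
POLD1,19,50384290
AKT1,14,104769349
RB1,13,48303748
NF1,17,31094927
PTEN,10,87863113
KDM6A,X,44873182
DNMT3A,2,25232961
TET2,4,105145875
ASXL1,20,32358062
JAK2,9,4984390
NRG1,8,31639386
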