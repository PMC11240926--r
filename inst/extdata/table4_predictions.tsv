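id	tool	score
KAB4_OLDAF	ACPred	98.60%
KAB4_OLDAF	ACPred-FL	98.11%
KAB4_OLDAF	AntiCP	72.58%
KAB4_OLDAF	AntiCP2	96.00%
KAB4_OLDAF	iACP	99.73%
KAB4_OLDAF	mACPpred	98.17%
KAB4_OLDAF	Our Model	99.60%
CYO22_VIOOD	ACPred	99.50%
CYO22_VIOOD	ACPred-FL	95.12%
CYO22_VIOOD	AntiCP	71.77%
CYO22_VIOOD	AntiCP2	95.00%
CYO22_VIOOD	iACP	99.90%
CYO22_VIOOD	mACPpred	98.42%
CYO22_VIOOD	Our Model	99.70%
THN2_VISAL	ACPred	99.50%
THN2_VISAL	ACPred-FL	99.22%
THN2_VISAL	AntiCP	70.56%
THN2_VISAL	AntiCP2	94.00%
THN2_VISAL	iACP	99.52%
THN2_VISAL	mACPpred	96.51%
THN2_VISAL	Our Model	96.60%
CYH3_VIOHE	ACPred	98.70%
CYH3_VIOHE	ACPred-FL	92.89%
CYH3_VIOHE	AntiCP	71.77%
CYH3_VIOHE	AntiCP2	95.00%
CYH3_VIOHE	iACP	99.80%
CYH3_VIOHE	mACPpred	98.80%
CYH3_VIOHE	Our Model	99.50%
MYX_CRODR	ACPred	99.60%
MYX_CRODR	ACPred-FL	99.22%
MYX_CRODR	AntiCP	70.56%
MYX_CRODR	AntiCP2	91.00%
MYX_CRODR	iACP	99.83%
MYX_CRODR	mACPpred	94.71%
MYX_CRODR	Our Model	95.10%
KAB10_OLDAF	ACPred	99.40%
KAB10_OLDAF	ACPred-FL	98.11%
KAB10_OLDAF	AntiCP	70.56%
KAB10_OLDAF	AntiCP2	90.00%
KAB10_OLDAF	iACP	99.93%
KAB10_OLDAF	mACPpred	98.48%
KAB10_OLDAF	Our Model	99.60%
PROTO_POLPI	ACPred	97.80%
PROTO_POLPI	ACPred-FL	99.22%
PROTO_POLPI	AntiCP	95.16%
PROTO_POLPI	AntiCP2	54.00%
PROTO_POLPI	iACP	88.85%
PROTO_POLPI	mACPpred	98.35%
PROTO_POLPI	Our Model	99.50%
CYO23_VIOOD	ACPred	99.70%
CYO23_VIOOD	ACPred-FL	98.11%
CYO23_VIOOD	AntiCP	70.56%
CYO23_VIOOD	AntiCP2	87.00%
CYO23_VIOOD	iACP	99.93%
CYO23_VIOOD	mACPpred	98.47%
CYO23_VIOOD	Our Model	99.60%
CYPLE_PSYLE	ACPred	99.90%
CYPLE_PSYLE	ACPred-FL	99.22%
CYPLE_PSYLE	AntiCP	68.95%
CYPLE_PSYLE	AntiCP2	87.00%
CYPLE_PSYLE	iACP	99.97%
CYPLE_PSYLE	mACPpred	96.86%
CYPLE_PSYLE	Our Model	99.70%
CYPLD_PSYBR	ACPred	98.10%
CYPLD_PSYBR	ACPred-FL	95.12%
CYPLD_PSYBR	AntiCP	72.18%
CYPLD_PSYBR	AntiCP2	87.00%
CYPLD_PSYBR	iACP	98.28%
CYPLD_PSYBR	mACPpred	98.01%
CYPLD_PSYBR	Our Model	99.50%
ATOX_PHYTB	ACPred	91.90%
ATOX_PHYTB	ACPred-FL	99.22%
ATOX_PHYTB	AntiCP	83.47%
ATOX_PHYTB	AntiCP2	50.00%
ATOX_PHYTB	iACP	96.44%
ATOX_PHYTB	mACPpred	96.64%
ATOX_PHYTB	Our Model	91.10%
CR12_RANCA	ACPred	99.30%
CR12_RANCA	ACPred-FL	98.11%
CR12_RANCA	AntiCP	70.16%
CR12_RANCA	AntiCP2	84.00%
CR12_RANCA	iACP	99.79%
CR12_RANCA	mACPpred	98.62%
CR12_RANCA	Our Model	86.10%
KAB14_OLDAF	ACPred	88.70%
KAB14_OLDAF	ACPred-FL	83.42%
KAB14_OLDAF	AntiCP	71.77%
KAB14_OLDAF	AntiCP2	86.00%
KAB14_OLDAF	iACP	99.76%
KAB14_OLDAF	mACPpred	97.94%
KAB14_OLDAF	Our Model	99.00%
CYPLC_PSYLE	ACPred	95.70%
CYPLC_PSYLE	ACPred-FL	98.11%
CYPLC_PSYLE	AntiCP	68.15%
CYPLC_PSYLE	AntiCP2	83.00%
CYPLC_PSYLE	iACP	99.25%
CYPLC_PSYLE	mACPpred	98.21%
CYPLC_PSYLE	Our Model	99.40%
CYPLB_PSYLE	ACPred	95.10%
CYPLB_PSYLE	ACPred-FL	98.11%
CYPLB_PSYLE	AntiCP	67.74%
CYPLB_PSYLE	AntiCP2	83.00%
CYPLB_PSYLE	iACP	99.43%
CYPLB_PSYLE	mACPpred	97.87%
CYPLB_PSYLE	Our Model	99.50%
GRAB_GRASX	ACPred	100.00%
GRAB_GRASX	ACPred-FL	99.22%
GRAB_GRASX	AntiCP	85.08%
GRAB_GRASX	AntiCP2	69.00%
GRAB_GRASX	iACP	82.43%
GRAB_GRASX	mACPpred	96.20%
GRAB_GRASX	Our Model	98.90%
CIRF_CHAPA	ACPred	99.60%
CIRF_CHAPA	ACPred-FL	82.67%
CIRF_CHAPA	AntiCP	75.81%
CIRF_CHAPA	AntiCP2	89.00%
CIRF_CHAPA	iACP	99.80%
CIRF_CHAPA	mACPpred	98.54%
CIRF_CHAPA	Our Model	99.50%
CYVNA_VIOIN	ACPred	99.60%
CYVNA_VIOIN	ACPred-FL	98.11%
CYVNA_VIOIN	AntiCP	71.37%
CYVNA_VIOIN	AntiCP2	82.00%
CYVNA_VIOIN	iACP	99.80%
CYVNA_VIOIN	mACPpred	98.12%
CYVNA_VIOIN	Our Model	99.50%
PNG1_PANCL	ACPred	99.90%
PNG1_PANCL	ACPred-FL	99.22%
PNG1_PANCL	AntiCP	81.85%
PNG1_PANCL	AntiCP2	58.00%
PNG1_PANCL	iACP	99.20%
PNG1_PANCL	mACPpred	98.22%
PNG1_PANCL	Our Model	99.00%
PSMA3_STAAN	ACPred	98.60%
PSMA3_STAAN	ACPred-FL	97.98%
PSMA3_STAAN	AntiCP	75.81%
PSMA3_STAAN	AntiCP2	82.00%
PSMA3_STAAN	iACP	96.15%
PSMA3_STAAN	mACPpred	87.97%
PSMA3_STAAN	Our Model	85.70%
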