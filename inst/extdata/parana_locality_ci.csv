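locality,method,CIe,CIe_sd,CIb,CIb_sd,CIa,CIa_sd,CIsq,CIsq_sd,CIr,CIr_sd
lgar,gillnet,0.67,0.16,0.64,0.15,0.6,0.1,0.59,0.09,0.55,0.07
rbai,gillnet,0.66,0.15,0.63,0.12,0.59,0.08,0.58,0.08,0.54,0.08
lgua,gillnet,0.64,0.18,0.61,0.16,0.58,0.1,0.57,0.11,0.55,0.07
lpat,gillnet,0.61,0.19,0.59,0.17,0.56,0.11,0.56,0.1,0.53,0.07
lven,gillnet,0.57,0.24,0.6,0.2,0.54,0.14,0.53,0.13,0.48,0.1
lfec,gillnet,0.54,0.17,0.55,0.16,0.52,0.1,0.52,0.1,0.5,0.09
lpve,gillnet,0.47,0.21,0.52,0.18,0.48,0.11,0.47,0.11,0.44,0.09
lfec,seine,0.45,0.32,0.45,0.29,0.48,0.22,0.45,0.24,0.5,0.19
rivi,gillnet,0.44,0.21,0.44,0.18,0.47,0.11,0.45,0.12,0.49,0.08
lgua,seine,0.44,0.38,0.45,0.37,0.45,0.3,0.43,0.3,0.46,0.26
lpat,seine,0.4,0.34,0.44,0.33,0.43,0.25,0.41,0.26,0.42,0.22
lgar,seine,0.39,0.37,0.43,0.36,0.42,0.27,0.39,0.28,0.4,0.24
lpve,seine,0.38,0.4,0.4,0.38,0.41,0.31,0.38,0.32,0.42,0.27
lven,seine,0.36,0.35,0.39,0.33,0.39,0.25,0.37,0.26,0.4,0.21
rpar,gillnet,0.17,0.17,0.26,0.2,0.28,0.14,0.26,0.14,0.3,0.1
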