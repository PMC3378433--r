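# EST-SSR canonical-class counts from the blueberry 454 unigene mining summary
# 87071 unique sequences >= 120 nt were mined
# tetra- and pentanucleotide counts are category totals carried by one stand-in class each
motif	count
CG	31
AC	530
AT	1347
AG	6034
AAC	177
AAG	1310
AAT	305
ACC	600
ACG	159
ACT	246
AGC	426
AGG	424
ATC	327
CCG	146
AAAC	2274
AAAAC	1550
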