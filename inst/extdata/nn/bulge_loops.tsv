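# Bulge-loop penalties by loop length (SantaLucia & Hicks 2004, Annu Rev
# Biophys Biomol Struct 33:415, loop-increment table). Published as free
# energy at 37 C (kcal/mol) with the enthalpy contribution taken as zero, so
# ds = -dg37 * 1000 / 310.15 cal/(mol*K). Lengths between tabulated points
# are interpolated linearly by the engine; the single-base bulge keeps the
# intervening Watson-Crick stack of its flanking pairs (closing-stack rule).
length	dg37
1	4.0
2	2.9
3	3.1
4	3.2
5	3.3
6	3.5
7	3.7
8	3.9
9	4.1
10	4.3
12	4.5
14	4.8
16	5.0
18	5.2
20	5.3
25	5.6
30	5.9
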