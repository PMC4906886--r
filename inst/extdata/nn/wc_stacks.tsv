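# Watson-Crick nearest-neighbor stack parameters, unified oligonucleotide set
# (SantaLucia 1998, PNAS 95:1460; SantaLucia & Hicks 2004, Annu Rev Biophys 33:415).
# Key: top dimer 5'->3' "/" bottom dimer 3'->5'. dh kcal/mol, ds cal/(mol*K).
# All 16 orientations listed; symmetric pairs repeat the same published value.
step	dh	ds
AA/TT	-7.9	-22.2
TT/AA	-7.9	-22.2
AT/TA	-7.2	-20.4
TA/AT	-7.2	-21.3
CA/GT	-8.5	-22.7
TG/AC	-8.5	-22.7
GT/CA	-8.4	-22.4
AC/TG	-8.4	-22.4
CT/GA	-7.8	-21.0
AG/TC	-7.8	-21.0
GA/CT	-8.2	-22.2
TC/AG	-8.2	-22.2
CG/GC	-10.6	-27.2
GC/CG	-9.8	-24.4
GG/CC	-8.0	-19.9
CC/GG	-8.0	-19.9
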