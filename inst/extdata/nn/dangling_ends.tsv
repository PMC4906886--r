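# Single dangling-end nearest-neighbor parameters (Bommarito, Peyret &
# SantaLucia 2000, Nucleic Acids Res 28:1929).
# Key: top dimer 5'->3' "/" bottom dimer 3'->5'; "." marks the strand without
# a base in that column. "XY/.Z" is a 5' dangle X on the top strand next to
# the pair Y:Z; ".X/YZ" is a 3' dangle Y on the bottom strand next to the
# pair X:Z. The two remaining geometries (3' top dangle, 5' bottom dangle)
# are the strand-flipped images of these and are resolved by the symmetric
# lookup in the engine. dh kcal/mol, ds cal/(mol*K).
step	dh	ds
# 5' dangling end on top strand
AA/.T	0.2	2.3
AC/.G	-6.3	-17.1
AG/.C	-3.7	-10.0
AT/.A	-2.9	-7.6
CA/.T	0.6	3.3
CC/.G	-4.4	-12.6
CG/.C	-4.0	-11.9
CT/.A	-4.1	-13.0
GA/.T	-1.1	-1.6
GC/.G	-5.1	-14.0
GG/.C	-3.9	-10.9
GT/.A	-4.2	-15.0
TA/.T	-6.9	-20.0
TC/.G	-4.0	-10.9
TG/.C	-4.9	-13.8
TT/.A	-0.2	-0.5
# 3' dangling end on bottom strand
.A/AT	-0.7	-0.8
.A/CT	4.4	14.9
.A/GT	-1.6	-3.6
.A/TT	2.9	10.4
.C/AG	-2.1	-3.9
.C/CG	-0.2	-0.1
.C/GG	-3.9	-11.2
.C/TG	-4.4	-13.1
.G/AC	-5.9	-16.5
.G/CC	-2.6	-7.4
.G/GC	-3.2	-10.4
.G/TC	-5.2	-15.0
.T/AA	-0.5	-1.1
.T/CA	4.7	14.2
.T/GA	-4.1	-13.1
.T/TA	-3.8	-12.6
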