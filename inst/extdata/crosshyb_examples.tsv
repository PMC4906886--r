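# Case-encoded probe/nontarget duplex reports for seven 50-mer probes from a
# legacy BLAST-screened bacterial whole-genome tiling array. Each duplex
# string is 100 characters: first 50 = probe top strand 5'->3', last 50 =
# nontarget counter strand 3'->5', column-aligned; uppercase columns are
# complementary base pairs, lowercase columns are mismatches. All seven rows
# share identity 24 bp and longest complementary stretch 14 bp yet span a
# wide nontarget melting-temperature range, which is why audits rank
# nontargets by Tm rather than by identity. Tm values (C) are as reported by
# the original thermodynamic screen of that probe set.
duplex	tm_nontarget	tm_target
tagagtagAAaaaCAAataAaAGAcattaaAGAAAATGATTTTTgattTttgtgttagTTaccGTTacgTgTCTcacgccTCTTTTACTAAAAAaagtAt	28.39	55.14
CTtgAaaTtgaaTacAaattctaTaaaTCAATGATATGAATacaataACAGAtgTggAtagaAgcTacctcgaAgggAGTTACTATACTTActcaccTGT	29.92	54.33
TcaAAgtctAtgatAttcgacAtAtaaTctTGAATCGAAAAAACaGCctcAagTTtctcTtaccTgtctgaTgTtgaAatACTTAGCTTTTTTGaCGcct	38.04	61.27
cGGTGCTCGATACGAttGCcCtgatgcTGacaaggCttctaTcgAaTCtcaCCACGAGCTATGCTctCGaGggccacACaagcggGttccgAagTaAGga	48.01	72.36
agcagTcgCtAcCGcttgcCGGACGAATTGCCGgTCGctccTgtttGggcctaaaAaaGcTcGCattttGCCTGCTTAACGGCaAGCacaaAaggcCttt	58.02	80.75
AacGgAGAaggaGagTgCcgggcGGAAGCCGGCGGCGaaaaCgTccaccgTgcCgTCTaggaCatAgGcttacCCTTCGGCCGCCGCacggGtActgcta	64.30	82.65
gGCCGGTGGCGGCCGtGagatgtcgctctCggcGAatgGCatTctgAtCTaCGGCCACCGCCGGCtCaaatgttatctcGgaaCTacaCGctAcggTgGA	68.56	80.10
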