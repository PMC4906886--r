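# Duplex initiation and terminal-pair terms, unified set (SantaLucia 1998).
# Published per-end terms: terminal G.C end dh 0.1 ds -2.8; terminal A.T end
# dh 2.3 ds 4.1. Expressed here as a per-duplex initiation (two G.C ends)
# plus an A.T penalty applied once per terminal A.T pair, which reproduces
# the per-end formulation exactly.
term	dh	ds
initiation	0.2	-5.6
terminal_AT	2.2	6.9
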