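# Duplex-level constants for the nearest-neighbor model, 37 C, kcal/mol.
# duplex_init and terminal_au are the Turner 2004 published values
# (duplex initiation +4.09; terminal A:U helix-end penalty +0.45); the
# terminal G:U end is treated like A:U. The mismatch penalties are this
# package's generic internal-loop constants (the loop model is configurable;
# see duplex_free_energy()): an isolated mismatch is scored as a 1x1
# internal loop, two consecutive mismatches as a 2x2 loop, and each further
# consecutive mismatch adds mismatch_ext.
name	value
duplex_init	4.09
terminal_au	0.45
terminal_gu	0.45
mismatch_1x1	1.70
mismatch_2x2	2.80
mismatch_ext	0.50
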