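# Engine parameter overrides for circmir (see ?read_engine_config).
# One "key = value" per line; '#' starts a comment. Values shown here are the
# package defaults, i.e. this file as shipped changes nothing.

# -- exact seed-match engine (TS) --------------------------------------------
ts.offset6 = FALSE          # also report offset-6mer (positions 3-8) sites

# -- duplex MFE engine (RH) ---------------------------------------------------
rh.e_threshold = -20        # report duplexes at or below this dG (kcal/mol)
init = 4.09                 # duplex initiation cost (kcal/mol)
max_loop = 15               # max unpaired nt on one side of a bulge/loop

# Stacking free energies are overridable pair-by-pair; the duplex-reversal
# symmetric entry is set together. Pairs: AU UA GC CG GU UG.
# stack.GC.GC = -3.26

# -- local alignment engine (M) ----------------------------------------------
m.match = 5                 # Watson-Crick pair score
m.wobble = 1                # G:U wobble score
m.mismatch = -3
m.gap_open = -9             # first gapped residue
m.gap_extend = -4           # each additional gapped residue
m.scale = 4                 # multiplier on substitution scores at seed positions
m.scale_from = 2            # first scaled miRNA position
m.scale_to = 8              # last scaled miRNA position
m.score_threshold = 140     # minimum alignment score to report
m.e_threshold = -1          # duplex dG filter on each alignment footprint
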