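# Transmembrane helix ranges (author residue numbering) for the two index
# sequences, labelled by bundle helix A-D.  VKORC1 threads CDAB (sequence
# helices 1-4 carry labels C, D, A, B), DsbB threads ABCD, so both families'
# redox-active CXXC motifs (VKORC1 Cys132-Cys135, DsbB Cys41-Cys44) fall in
# the loop of the AB module.  Boundaries follow the structure-based topology
# of the respective families and are deliberately explicit and editable:
# module definitions depend on them.
VKORC1_HUMAN:
  C: [14, 35]    # sequence TM1, before the large lumenal loop (Asp36-Ser79)
  D: [80, 102]   # sequence TM2
  A: [107, 129]  # sequence TM3 (carries Ser117, Leu124)
  B: [133, 152]  # sequence TM4 (carries Thr138)
DSBB_ECOLI:
  A: [15, 32]    # sequence TM1
  B: [45, 63]    # sequence TM2
  C: [71, 89]    # sequence TM3
  D: [145, 162]  # sequence TM4 (core domain ends at Ile162)
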