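# Interaction target specification.
# targets: residues of interest (chain:resseq[:icode]); one entry for a
# single-point analysis, two for a double-point pair.
# chains: partner class of each chain (Ab = antibody, Ag = antigen);
# waters are classed S automatically.
targets:
  - H:57
chains:
  H: Ab
  L: Ab
  T: Ag
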