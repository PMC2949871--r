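# Default six-helix carrier topology used by the synthetic-data generator.
# A faithful *shape* of the carrier fold (six 20-column transmembrane
# helices, matrix-facing loops 1/3/5, cytosol-facing termini and loops 2/4,
# signature-motif anchors at the matrix-side C-termini of the odd helices),
# not the boundary columns of any particular curated alignment. Edit or
# replace to match your own alignment.
alignment_width: 200
helices:
  - {start: 11, end: 30}
  - {start: 43, end: 62}
  - {start: 75, end: 94}
  - {start: 107, end: 126}
  - {start: 139, end: 158}
  - {start: 171, end: 190}
# splits omitted -> vertical midpoint of each helix
# up_first omitted -> odd helices cytosol-to-matrix, even helices reversed
loops:
  "n": {start: 1, end: 10}
  loop1: {start: 31, end: 42}
  loop2: {start: 63, end: 74}
  loop3: {start: 95, end: 106}
  loop4: {start: 127, end: 138}
  loop5: {start: 159, end: 170}
  "c": {start: 191, end: 200}
motif_anchors: [25, 89, 153]
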