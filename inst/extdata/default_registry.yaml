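# Default DEP registry.
#
# Positions are given in mature-protein coordinates (position 1 = first
# residue after the leader peptide).  Each position may declare explicit
# serological equivalence classes; residues not listed in any class fall
# into an implicit singleton class of their own.  Positions 11 and 67 are
# carried from earlier assignment criteria without full class definitions,
# so each residue there is its own class.  Position "82-83" is a paired
# motif: the two sites are read jointly (the LR motif marks Bw4).
locus_groups:
  classI:
    loci: [A, B, C]
    positions:
      - id: "11"
      - id: "67"
      - id: "69"
      - id: "71"
      - id: "82-83"
        sites: [82, 83]
        classes:
          - [LR]
      - id: "103"
        classes:
          - [L]
          - [V]
          - [M]
      - id: "107"
      - id: "109"
        classes:
          - [F]
          - [L]
      - id: "163"
      - id: "166"
      - id: "167"
        classes:
          - [G, S]
          - [W]
      - id: "171"
    # Registered as explicitly non-DEP: excluded from signatures even if
    # residue data are available for them.
    non_dep: [97, 114, 116, 152]
  DPB1:
    loci: [DPB1]
    positions:
      - id: "96"
        classes:
          - [R]
          - [K]
      # R and K at position 69 behave as serologically equivalent.
      - id: "69"
        classes:
          - [R, K]
  DRB:
    loci: [DRB1, DRB3, DRB4, DRB5]
    positions:
      # R/K dimorphism at 71 does not split serotypes.
      - id: "71"
        classes:
          - [R, K]
# Positions treated as still-pending for the SEROTYPE category.  Empty in
# the default (current) registry; a pre-update registry can list
# e.g. ["103", "109"] here to reproduce the earlier SEROTYPE state.
pending:
  classI: []
  DPB1: []
  DRB: []
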