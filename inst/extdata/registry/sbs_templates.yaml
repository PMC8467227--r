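# Solved-structure templates with experimentally identified surface binding
# sites (SBSs). Residue numbering: mature = signal peptide removed,
# precursor = full translated product; where a structure is numbered on the
# mature chain only, the two coincide.
#
# 2GVY is an alias for 2GUY (both codes are in circulation for the same
# A. niger structure). For 6TOZ the second SBS residue has two published
# readings (Y358 and Y368 in precursor-style numbering); Y358 is stored as
# canonical and Y368 retained as variant_precursor.
templates:
  - pdb_code: "2GUY"
    aliases: ["2GVY"]
    subfamily: GH13_1
    source_organism: "Aspergillus niger"
    sites:
      - site: SBS-I
        residues:
          - {letter: "Y", mature: 382, precursor: 402}
          - {letter: "W", mature: 385, precursor: 405}
  - pdb_code: "2GJP"
    aliases: []
    subfamily: GH13_5
    source_organism: "Bacillus halmapalus"
    sites:
      - site: SBS-I
        residues:
          - {letter: "W", mature: 439, precursor: 439}
          - {letter: "W", mature: 469, precursor: 469}
      - site: SBS-II
        residues:
          - {letter: "W", mature: 347, precursor: 347}
      - site: SBS-III
        residues:
          - {letter: "Y", mature: 363, precursor: 363}
  - pdb_code: "6TOZ"
    aliases: []
    subfamily: GH13_5
    source_organism: "Bacillus paralicheniformis"
    sites:
      - site: SBS-I
        residues:
          - {letter: "F", mature: 257, precursor: 257}
          - {letter: "Y", mature: 358, precursor: 358, variant_precursor: 368}
  - pdb_code: "3BC9"
    aliases: []
    subfamily: GH13_5
    source_organism: "Halothermothrix orenii"
    sites:
      - site: SBS-I
        residues:
          - {letter: "Y", mature: 460, precursor: 484}
          - {letter: "W", mature: 488, precursor: 512}
      - site: SBS-II
        residues:
          - {letter: "W", mature: 260, precursor: 284}
          - {letter: "W", mature: 287, precursor: 311}
      - site: SBS-III
        residues:
          - {letter: "W", mature: 306, precursor: 330}
          - {letter: "W", mature: 310, precursor: 334}
  - pdb_code: "3BLP"
    aliases: []
    subfamily: GH13_24
    source_organism: "Homo sapiens (saliva)"
    sites:
      - site: SBS-I
        residues:
          - {letter: "Y", mature: 276, precursor: 291}
          - {letter: "W", mature: 284, precursor: 299}
      - site: SBS-II
        residues:
          - {letter: "W", mature: 316, precursor: 331}
          - {letter: "W", mature: 388, precursor: 403}
      - site: SBS-III
        residues:
          - {letter: "W", mature: 203, precursor: 218}
      - site: SBS-IV
        residues:
          - {letter: "W", mature: 134, precursor: 149}
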