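# Site inventory for the mature mouse osteocalcin chain (1-based positions).
disulfide_bonds:
  - [19, 25]
gla_sites: [13, 17, 20]
glycosites: [5, 8, 15]
# Fully carboxylated (3x Gla), disulfide-formed theoretical monoisotopic mass.
anchor_mass_da: 5243.45
anchor_gla_count: 3
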