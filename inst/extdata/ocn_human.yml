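# Site inventory for the mature human osteocalcin chain (1-based positions).
# The chain contains no serine or threonine, so the glycosite list is empty.
disulfide_bonds:
  - [23, 29]
gla_sites: [17, 21, 24]
glycosites: []
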