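# Two-locus gametophytic incompatibility fit for a 90-plant selfed
# population scored at two unlinked marker loci.
expect:
  parent: AB|AB
  selection:
    pattern: B|A
    sex: male
    penetrance: 1
  n: 90
gof:
  file: table1_observed.csv
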