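# Transgene-rescue segregation: each line's double-null plant count
# (vs all other plants) compared with the vector control by Fisher's
# exact test, plus a copy-number profile for the control family.
fisher:
  alternative: two.sided
  tables:
    RPC4_DGS1_T65: [[10, 58], [1, 93]]
    RPC4c_DGS2_nivara: [[15, 65], [1, 93]]
    RPC4d_DGS2_nivara: [[18, 55], [1, 93]]
    RPC4e_DGS2_nivara: [[6, 22], [1, 93]]
copies:
  counts: [45, 48, 1]
  max_c: 3
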