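utils::globalVariables(c(
  ".", ".N", ".SD", "N", "class", "containment", "end", "genome_id", "kmer",
  "mm", "off", "oriented_seq", "pos", "read", "read_id", "ref", "ref_id",
  "seq", "start", "strand", "target"
))
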