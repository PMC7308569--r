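Optional local data
===================

Place `srv_genome_segments.fasta` here (a deposited 10-segment RNA virus
genome, 35,412 nt in total, retrievable from the DDBJ/GenBank nucleotide
repository) to enable the deposited-genome roster check in the test suite.
No third-party data are shipped with the package.
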