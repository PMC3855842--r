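# Example run configuration for run_integrate() / prokannot-cli integrate.
# Paths resolve relative to this file's directory unless absolute.
organism: "Example organism"
predictors:
  prodigal: predictions/prodigal.gff3
  genemark: predictions/genemark.gff3
  mga: predictions/mga.gff3
rna:
  - predictions/rnammer.gff3
  - predictions/trnascan.gff3
homology:
  uniprot: hits/uniprot.tsv
  nr: hits/nr.tsv
domains: hits/interproscan.tsv
consensus:
  min_cds_len: 90
  orphan_policy: keep
  max_rna_overlap: 0
products:
  db_precedence: [uniprot, nr, kegg, cdd]
  max_evalue: 1.0e-5
  min_identity: 30
  min_query_cov: 0.5
gbt:
  db: nr
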