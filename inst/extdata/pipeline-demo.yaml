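# Minimal pipeline configuration. Unset fields take the protocol defaults
# (see validate_config()). Paths point at a fixture directory written by
# write_fixtures() or the CLI `simulate` command.
inputs:
  vcf: fixtures/genotypes.vcf
  mtx: fixtures/counts.mtx
  cells: fixtures/cells.tsv
  genes: fixtures/genes.tsv
  gwas:
    demo: fixtures/gwas_demo.tsv
pseudobulk:
  min_donors: 15          # study default is 40; small demo cohorts need less
mapping:
  n_pcs: 5                # study default is 20; cap well below donor count
  interaction_min_group_donors: 5
coloc:
  min_shared: 10          # study default is 100 shared variable SNPs
seed: 2023
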