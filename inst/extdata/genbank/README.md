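# Deposited reference sequences (user-supplied)

The flatfish analyses in `analysis/07_reference_data.R` and the final
blocks of `tests/testthat/test-acceptance.R` run on the deposited GenBank
records. They are not redistributed with the package; download them (e.g.
via NCBI efetch, `rettype=fasta`) and place them here as:

| file | accessions | content |
|---|---|---|
| `stone_flounder_cdna.fasta` | JX645176-JX645186 | 11 stone flounder MHC class II B cDNA alleles |
| `stone_flounder_wholelength.fasta` | KF535998-KF536005 | 8 whole-length genomic alleles of individual No. 3 |
| `stone_flounder_partial.fasta` | KF536006-KF536025 | partial (exon 1-4) genomic alleles, 8 individuals |
| `japanese_flounder_gdna.fasta` | KJ784489 | Japanese flounder genomic sequence |
| `japanese_flounder_cdna.fasta` | KJ784490-KJ784493 | 4 Japanese flounder cDNA alleles |

Example download of one set:

```sh
curl -o stone_flounder_cdna.fasta \
  'https://eutils.ncbi.nlm.nih.gov/entrez/eutils/efetch.fcgi?db=nuccore&id=JX645176,JX645177,JX645178,JX645179,JX645180,JX645181,JX645182,JX645183,JX645184,JX645185,JX645186&rettype=fasta&retmode=text'
```

Individual-of-origin tags (`individual=<id>` appended to a FASTA header,
or a sidecar TSV `clone_id  individual_id  source`) are needed only for
analyses that use the genotype table, such as the diploid-constrained
grouping of the partial alleles.
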