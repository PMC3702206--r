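{
  "_comment": "Synthetic SOCS1-like reference. The coding sequence and the exact domain aa boundaries are editable stand-ins; domain identities, CDS length (636), transcript offset (705) and the C-terminal set {NLS, SOCS box} follow the published gene model.",
  "gene_symbol": "SOCS1",
  "cds": {
    "fasta": "synthetic_socs1_cds.fa"
  },
  "cds_offset_in_exon2": 705,
  "domains": [
    {
      "name": "SH3",
      "aa_start": 10,
      "aa_end": 40,
      "is_cterminal": false
    },
    {
      "name": "JAK",
      "aa_start": 56,
      "aa_end": 155,
      "is_cterminal": false
    },
    {
      "name": "KIR",
      "aa_start": 56,
      "aa_end": 66,
      "is_cterminal": false
    },
    {
      "name": "SH2",
      "aa_start": 79,
      "aa_end": 155,
      "is_cterminal": false
    },
    {
      "name": "NLS",
      "aa_start": 159,
      "aa_end": 171,
      "is_cterminal": true
    },
    {
      "name": "SOCS box",
      "aa_start": 172,
      "aa_end": 211,
      "is_cterminal": true
    }
  ],
  "upstream_context": "TTATTCCACCCCCGGACGCT",
  "downstream_context": "GGCGGGCGTGGAGTAAAAAA"
}
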