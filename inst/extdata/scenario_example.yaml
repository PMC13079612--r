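# Example scenario for the domkit command-line wrapper (desk scale).
architecture: polygenic
nominal_pdv: 0.3
nominal_H2: 0.7
n_chr: 5
n_snp_per_chr: 120
n_qtl_per_chr: 12
n_founders: 400
n_female: 50
n_male: 8
seed: 42
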