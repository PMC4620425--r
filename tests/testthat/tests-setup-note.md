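Helpers: `helper-oracles.R` holds brute-force oracles (naive pixel sums,
pairwise AUC, exhaustive weak-learner search, full loop replay) that never
touch the fast code paths they validate. All fixtures are generated in code
under fixed seeds.
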