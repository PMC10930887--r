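Illustrative gene lists only. These files carry plausible human gene
symbols for a senescence core signature, a SASP secretome signature,
and oscillatory-hypoxia up-/down-regulated sets, but they are SYNTHETIC
placeholders assembled for examples and tests -- not the curated lists
any published analysis used. Substitute your own curated lists (one
gene symbol per line) for real analyses.
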