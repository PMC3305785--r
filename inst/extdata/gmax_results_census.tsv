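quantity	value
total_unique_hits	63841
within_te_hits	51154
within_intact_gmr9_hits	40150
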