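{"n_proteins":24,"n_sites":120,"n_positive":44,"n_negative":76}
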