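database	n_identified	n_total
regional	342	473
global_98	162	473
global_98.5	134	473
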