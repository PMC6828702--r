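100..400
complement(500..800)
join(900..950,960..1000)
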