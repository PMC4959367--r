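# semantically negative words (one per line, editable)
fail
fails
failed
lack
lacks
lacked
absence
absent
unable
without
never
no
neither
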