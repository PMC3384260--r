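# default meronym head nouns (subunit-complex vocabulary)
complex
dimer
subunit
heterodimer
homodimer
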