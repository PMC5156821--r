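note_id	term
example_note	thrombocytosis
example_note	Crohn disease
example_note	budesonide
example_note	diabetes mellitus
example_note	metformin
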