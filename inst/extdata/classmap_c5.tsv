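form	tag_pattern	word_class	content_subtype
well	^AV	insert	none
so	^AV	insert	none
	^ITJ	insert	none
	^AJ	content	adjective
	^AV	content	adverb
	^NN	content	noun
	^NP0	content	noun
	^VV	content	lexical_verb
	.	function	none
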