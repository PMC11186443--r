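form	tag_pattern	word_class	content_subtype
well	^R	insert	none
so	^R	insert	none
	^UH	insert	none
	^JJ|^JK	content	adjective
	^R[AEGLPRT]	content	adverb
	^N[DNP]	content	noun
	^VV	content	lexical_verb
	.	function	none
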