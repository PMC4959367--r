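# verb lemma <TAB> relation-verb class (editable seed lexicon)
reduce	DOWN_REGULATE
reduces	DOWN_REGULATE
reduced	DOWN_REGULATE
inhibit	DOWN_REGULATE
inhibits	DOWN_REGULATE
inhibited	DOWN_REGULATE
suppress	DOWN_REGULATE
suppressed	DOWN_REGULATE
decrease	DOWN_REGULATE
decreased	DOWN_REGULATE
increase	UP_REGULATE
increases	UP_REGULATE
increased	UP_REGULATE
induce	UP_REGULATE
induces	UP_REGULATE
induced	UP_REGULATE
enhance	UP_REGULATE
enhanced	UP_REGULATE
activate	UP_REGULATE
activates	UP_REGULATE
activated	UP_REGULATE
cause	CAUSE
causes	CAUSE
caused	CAUSE
regulate	REGULATE
regulates	REGULATE
regulated	REGULATE
associate	ASSOCIATE
associated	ASSOCIATE
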