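# Mapping from embedding predications to event / modification types.
# Columns: tracks (comma-sep) <TAB> predication type <TAB> polarity
# constraint <TAB> modality value constraint <TAB> output type <TAB> source.
# '-' means unconstrained. MV constraints: '>x', '>=x', '<x', '<=x', '=x'.
# source is 'core' for rows taken directly from the published mapping table,
# 'extension' for rows added to cover the worked examples consistently.
GENIA,ID	CAUSAL	neutral	-	REGULATION	core
GENIA,ID,EPI	SUCCESS	negative	-	NEGATION	core
EPI	CAUSAL	positive	-	CATALYSIS	core
GENIA,ID,EPI	SPECULATIVE	-	>0.0	SPECULATION	core
GENIA,ID,EPI	DEMONSTRATIVE	negative	-	SPECULATION	core
GENIA,ID	CAUSAL	positive	-	POSITIVE_REGULATION	extension
GENIA,ID	CAUSAL	negative	-	NEGATIVE_REGULATION	extension
GENIA,ID,EPI	ASSUMPTIVE	-	>0.0	SPECULATION	extension
GENIA,ID,EPI	EPISTEMIC	negative	-	SPECULATION	extension
GENIA,ID,EPI	POTENTIAL	negative	-	NEGATION	extension
GENIA,ID,EPI	INTERROGATIVE	-	>0.0	SPECULATION	extension
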