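# Argument identification rules: relation type <TAB> POS <TAB> inclusions
# <TAB> exclusions <TAB> logical argument type. '-' means no constraint.
# Inclusion/exclusion constraints test the PREDICATE's lemma or semantic
# type. Rules apply in file order; the first match wins.
PREP_ON	NN	influence,impact,effect	-	Object
AGENT	VB	-	-	Subject
NSUBJPASS	VB	-	-	Object
WHETHER_COMP	VB	INTERROGATIVE	-	Object
PREP_IN	NN	-	effect,role,influence,importance	Adjunct
DOBJ	VB	-	-	Object
XCOMP	VB	-	-	Object
CCOMP	VB	-	-	Object
AUX	MD	-	-	Object
NSUBJ	VB	-	-	Subject
XSUBJ	VB	-	-	Subject
XSUBJ	JJ	-	-	Object
NSUBJ	JJ	-	-	Object
NSUBJPASS	JJ	-	-	Object
PREP_TO	VB	-	-	Object
PREP_OF	NN	-	effect,role,influence,importance	Object
PREP_BY	VB	-	-	Subject
PREPC_BY	VB	-	-	Adjunct
PREP_WITH	NN	-	-	Adjunct
PREP_FOR	JJ	-	-	Adjunct
PREP_INTO	NN	-	-	Adjunct
NN	NN	-	-	Object
POSS	NN	-	-	Object
AMOD	JJ	-	-	Object
ADVMOD	RB	-	-	Object
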