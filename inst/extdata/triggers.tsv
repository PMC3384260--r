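# Seed trigger lexicon: lemma <TAB> POS <TAB> semantic type <TAB> polarity
# <TAB> category strength <TAB> negative-raising.
# Blank polarity defaults to neutral, blank strength to 1.0, blank
# negative-raising to false.
#
# --- modal predicates -------------------------------------------------------
show	VB	DEMONSTRATIVE	positive	1.0	false
demonstrate	VB	DEMONSTRATIVE	positive	1.0	false
indicate	VB	DEMONSTRATIVE	positive	0.8	false
suggest	VB	SPECULATIVE	positive	0.6	false
appear	VB	SPECULATIVE	positive	0.6	false
seem	VB	SPECULATIVE	positive	0.6	false
may	MD	SPECULATIVE	positive	0.7	false
might	MD	SPECULATIVE	positive	0.6	false
possible	JJ	SPECULATIVE	positive	0.6	false
potential	JJ	SPECULATIVE	positive	0.6	false
presume	VB	ASSUMPTIVE	positive	0.7	false
assume	VB	ASSUMPTIVE	positive	0.7	false
unknown	JJ	EPISTEMIC	negative	0.7	false
think	VB	EPISTEMIC	positive	0.8	true
believe	VB	EPISTEMIC	positive	0.8	true
known	JJ	EPISTEMIC	positive	1.0	false
capable	JJ	POTENTIAL	positive	1.0	false
able	JJ	POTENTIAL	positive	1.0	false
unable	JJ	POTENTIAL	negative	1.0	false
can	MD	POTENTIAL	positive	0.9	false
should	MD	OBLIGATIVE	positive	0.7	false
must	MD	OBLIGATIVE	positive	0.9	false
try	VB	INTENTIONAL	positive	1.0	false
attempt	VB	INTENTIONAL	positive	1.0	false
examine	VB	INTERROGATIVE	positive	1.0	false
investigate	VB	INTERROGATIVE	positive	1.0	false
test	VB	INTERROGATIVE	positive	1.0	false
fail	VB	SUCCESS	negative	1.0	false
succeed	VB	SUCCESS	positive	1.0	false
manage	VB	SUCCESS	positive	1.0	false
# --- relational predicates --------------------------------------------------
lead	VB	CAUSAL	positive	1.0	false
induce	VB	CAUSAL	positive	1.0	false
cause	VB	CAUSAL	neutral	1.0	false
mediate	VB	CAUSAL	neutral	1.0	false
stimulate	VB	CAUSAL	positive	1.0	false
effect	NN	CAUSAL	neutral	0.5	false
prevention	NN	CAUSAL	negative	1.0	false
prevent	VB	CAUSAL	negative	1.0	false
inhibit	VB	CAUSAL	negative	1.0	false
coincide	VB	CORRELATIVE	positive	0.5	false
correlate	VB	CORRELATIVE	positive	0.5	false
compare	VB	COMPARATIVE	positive	1.0	false
important	JJ	SALIENCY	positive	1.0	false
role	NN	SALIENCY	neutral	0.5	false
subsequent	JJ	TEMPORAL	neutral	1.0	false
follow	VB	TEMPORAL	neutral	1.0	false
# --- attributive predicates -------------------------------------------------
undergo	VB	PATIENT	neutral	1.0	false
involve	VB	PATIENT	neutral	1.0	false
require	VB	PATIENT	neutral	1.0	false
# --- valence shifters -------------------------------------------------------
not	RB	NEGATOR	negative	1.0	false
no	DT	NEGATOR	negative	1.0	false
never	RB	NEGATOR	negative	1.0	false
lack	VB	NEGATOR	negative	1.0	false
absence	NN	NEGATOR	negative	1.0	false
without	IN	NEGATOR	negative	1.0	false
weakly	RB	DIMINISHER	neutral	1.0	false
slightly	RB	DIMINISHER	neutral	0.3	false
barely	RB	DIMINISHER	neutral	0.3	false
partially	RB	DIMINISHER	neutral	0.5	false
strongly	RB	INTENSIFIER	neutral	0.7	false
markedly	RB	INTENSIFIER	neutral	0.7	false
# --- atomic predicates (shared-task event types) ----------------------------
expression	NN	GENE_EXPRESSION			false
express	VB	GENE_EXPRESSION			false
production	NN	GENE_EXPRESSION			false
produce	VB	GENE_EXPRESSION			false
overexpression	NN	GENE_EXPRESSION	positive		false
synthesis	NN	GENE_EXPRESSION			false
transcription	NN	TRANSCRIPTION			false
transcribe	VB	TRANSCRIPTION			false
phosphorylation	NN	PHOSPHORYLATION			false
phosphorylate	VB	PHOSPHORYLATION			false
methylation	NN	METHYLATION			false
methylate	VB	METHYLATION			false
degradation	NN	PROTEIN_CATABOLISM			false
degrade	VB	PROTEIN_CATABOLISM			false
proteolysis	NN	PROTEIN_CATABOLISM			false
secretion	NN	LOCALIZATION			false
secrete	VB	LOCALIZATION			false
localization	NN	LOCALIZATION			false
translocation	NN	LOCALIZATION			false
binding	NN	BINDING			false
bind	VB	BINDING			false
interaction	NN	BINDING			false
interact	VB	BINDING			false
engagement	NN	BINDING			false
regulation	NN	REGULATION			false
regulate	VB	REGULATION			false
stimulation	NN	POSITIVE_REGULATION			false
activation	NN	POSITIVE_REGULATION			false
activate	VB	POSITIVE_REGULATION			false
upregulation	NN	POSITIVE_REGULATION	positive		false
increase	VB	POSITIVE_REGULATION	positive		false
increased	JJ	POSITIVE_REGULATION	positive		false
enhance	VB	POSITIVE_REGULATION	positive		false
suppression	NN	NEGATIVE_REGULATION	negative		false
downregulation	NN	NEGATIVE_REGULATION	negative		false
reduce	VB	NEGATIVE_REGULATION	negative		false
infection	NN	PROCESS			false
colonization	NN	PROCESS			false
virulence	NN	PROCESS			false
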