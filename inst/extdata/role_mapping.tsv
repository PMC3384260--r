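# Mapping logical arguments to semantic roles.
# Columns: logical argument <TAB> constrained-to event types (comma-sep or
# '-') <TAB> excluded event types <TAB> semantic role. First match wins, so
# the event-type-constrained mappings precede the generic ones.
Subject	BINDING	-	Theme
Object	PROCESS	-	Participant
Object	SPECULATION,NEGATION	-	Scope
Object	-	PROCESS	Theme
Subject	-	BINDING	Cause
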