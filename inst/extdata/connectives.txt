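# Illustrative discourse-connective lexicon.
# direction: cause-first  = the cause span precedes the connective
#            effect-first = the cause span follows the connective
because	effect-first
since	effect-first
as	effect-first
so	cause-first
therefore	cause-first
thus	cause-first
hence	cause-first
as a result	cause-first
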