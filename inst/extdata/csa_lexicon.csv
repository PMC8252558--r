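# csa-lexicon v1.0
# Phrase lexicon for rule-based detection of recorded childhood sexual abuse
# in free-text clinical notes. polarity: include = affirms a childhood
# history; exclude = negates or marks the mention as merely possible;
# indeterminate = a historical mention whose age at abuse cannot be
# confirmed (triggers patient removal from the analytic cohort).
# {AGE} matches a 1-2 digit age or an age range such as "6-9".
# User-extensible: add rows, keep pattern_id unique, bump the version above.
pattern_id,surface,polarity,notes
inc_childhood_sexual_abuse,childhood sexual abuse,include,core phrase
inc_history_sexual_abuse,history of sexual abuse,include,core phrase
inc_hx_sexual_abuse,hx of sexual abuse,include,abbreviated history
inc_childhood_hx_sexual_abuse,childhood hx of sexual abuse,include,abbreviated childhood history
inc_csa,csa,include,acronym
inc_abused_as_child,sexually abused as a child,include,core phrase
inc_abuse_as_child,sexual abuse as a child,include,variant
inc_abused_in_childhood,sexually abused in childhood,include,variant
inc_childhood_experiences,childhood experiences of sexual abuse,include,variant
inc_childhood_experience,childhood experience of sexual abuse,include,variant
inc_abuse_at_age,sexual abuse at age {AGE},include,age slot
inc_abused_at_age,sexually abused at age {AGE},include,age slot
inc_abused_at_the_age_of,sexually abused at the age of {AGE},include,age slot
inc_abused_between_ages,sexually abused between the ages of {AGE},include,age range slot
inc_abused_aged,sexually abused aged {AGE},include,age slot
exc_no_csa,no csa,exclude,negation
exc_nil_csa,nil csa,exclude,negation
exc_no_history_csa,no history of csa,exclude,negation
exc_denied_childhood_history,denied a childhood history of sexual abuse,exclude,negation
exc_denies_childhood_history,denies a childhood history of sexual abuse,exclude,negation
exc_denied_any_history,denied any history of sexual abuse,exclude,negation
exc_denies_any_history,denies any history of sexual abuse,exclude,negation
exc_denied_history,denied a history of sexual abuse,exclude,negation
exc_denies_history,denies a history of sexual abuse,exclude,negation
exc_no_history_sexual_abuse,no history of sexual abuse,exclude,negation
exc_no_childhood_sexual_abuse,no childhood sexual abuse,exclude,negation
exc_possible_history,possible history of sexual abuse,exclude,possible only
exc_possible_childhood,possible childhood sexual abuse,exclude,possible only
exc_possible_csa,possible csa,exclude,possible only
exc_query_csa,? csa,exclude,query marker
exc_query_childhood,? childhood sexual abuse,exclude,query marker
exc_query_history,? history of sexual abuse,exclude,query marker
ind_historical_sexual_abuse,historical sexual abuse,indeterminate,age at abuse unconfirmable
ind_historic_sexual_abuse,historic sexual abuse,indeterminate,age at abuse unconfirmable
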