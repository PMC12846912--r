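# Example universal specifications in the format read_universals() expects.
# Feature codes refer to columns of a binary trait matrix; conditions are
# conjunctions of feature=value literals, the result is a single literal.
- id: noun_num_adj
  utype: narrow_word_order
  condition:
    - {feature: N_before_Num, value: 1}
  result: {feature: N_before_Adj, value: 1}
  description: >
    If nouns precede numerals, nouns precede adjectives.
- id: adp_num_adj
  utype: narrow_word_order
  condition:
    - {feature: Adp_before_N, value: 1}
    - {feature: N_before_Num, value: 1}
  result: {feature: N_before_Adj, value: 1}
  description: >
    If a language is prepositional and nouns precede numerals, nouns
    precede adjectives (a conjunction-conditioned universal).
- id: obj_subj_indexing
  utype: hierarchy
  condition:
    - {feature: object_indexing, value: 1}
  result: {feature: subject_indexing, value: 1}
  description: >
    If the verb indexes the object, it also indexes the subject.
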