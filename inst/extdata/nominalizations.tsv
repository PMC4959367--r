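# seed list of nominalized biomedical verb forms (one per line, editable)
mutation
mutations
deletion
deletions
insertion
insertions
substitution
substitutions
inhibition
expression
association
activation
regulation
amplification
methylation
translocation
duplication
loss
development
screening
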