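# blacklisted head terms: constructs outside the database/software scope
format
file
algorithm
method
language
identifier
operating system
model
score
statistic
coefficient
matrix
distribution
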