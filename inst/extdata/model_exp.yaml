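# Reference study model: constant trend, unit variance, exponential
# correlation with inverse range 7 on the unit square.
family: exponential
nu: 7
trend: constant
sigma2: 1
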