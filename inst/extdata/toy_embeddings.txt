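# toy deterministic 8-dimensional term embeddings for the test fixtures
hpv 0.90 0.30 0.00 0.00 0.00 0.00 0.00 0.00
virus 1.00 0.20 0.00 0.00 0.00 0.00 0.00 0.00
disease 0.80 0.00 0.00 0.10 0.20 0.00 0.00 0.00
cancer 0.85 0.00 0.00 0.10 0.10 0.00 0.00 0.00
throat 0.30 0.00 0.00 0.60 0.00 0.00 0.00 0.20
measles 0.80 0.10 0.00 0.00 0.10 0.00 0.00 0.00
polio 0.80 0.10 0.00 0.00 0.10 0.00 0.00 0.05
vaccine 0.20 1.00 0.00 0.00 0.00 0.20 0.00 0.00
vaccination 0.20 0.95 0.00 0.00 0.00 0.20 0.00 0.00
shot 0.10 0.80 0.00 0.00 0.00 0.00 0.10 0.00
dose 0.00 0.70 0.00 0.00 0.00 0.00 0.60 0.00
insurance 0.00 0.00 1.00 0.00 0.00 0.30 0.00 0.00
plan 0.00 0.00 0.80 0.00 0.00 0.20 0.00 0.20
coverage 0.00 0.00 0.90 0.00 0.00 0.40 0.00 0.00
cover 0.00 0.10 0.50 0.00 0.00 0.90 0.00 0.00
insure 0.00 0.00 0.60 0.00 0.00 0.80 0.00 0.00
prevent 0.00 0.20 0.00 0.00 0.20 0.80 0.00 0.00
protect 0.00 0.20 0.00 0.00 0.10 0.85 0.00 0.00
affect 0.10 0.00 0.00 0.10 0.95 0.00 0.00 0.00
impact 0.00 0.00 0.00 0.00 0.90 0.00 0.00 0.10
cause 0.20 0.00 0.00 0.00 0.85 0.00 0.00 0.00
male 0.00 0.00 0.00 0.95 0.00 0.00 0.00 0.00
female 0.00 0.00 0.00 0.95 0.00 0.00 0.00 0.10
child 0.00 0.00 0.00 0.90 0.00 0.00 0.00 0.20
person 0.00 0.00 0.00 0.90 0.00 0.00 0.00 0.05
gender 0.00 0.00 0.00 0.85 0.00 0.00 0.00 0.15
target 0.10 0.00 0.00 0.40 0.30 0.00 0.00 0.30
count 0.00 0.00 0.00 0.00 0.00 0.00 0.90 0.00
number 0.00 0.00 0.00 0.00 0.00 0.00 0.95 0.00
age 0.00 0.00 0.00 0.30 0.00 0.00 0.50 0.40
need 0.00 0.10 0.10 0.00 0.30 0.20 0.00 0.50
require 0.00 0.10 0.10 0.00 0.30 0.20 0.00 0.55
minimum 0.00 0.00 0.00 0.00 0.00 0.00 0.80 0.20
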