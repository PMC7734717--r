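affect
answer
apply
ask
cause
cost
cover
expose
help
hurt
include
infect
insure
involve
matter
mean
need
prevent
protect
recommend
repeat
require
spread
tell
treat
vaccinate
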