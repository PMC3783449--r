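category,term
affect,happy
affect,glad
affect,sad
affect,love
affect,hate
affect,excit*
social,friend*
social,family
social,party
social,talk*
social,people
cogmech,think*
cogmech,know
cogmech,because
cogmech,reason*
negemo,sad
negemo,hate
negemo,angry
negemo,depress*
negemo,sick
posemo,happy
posemo,glad
posemo,love
posemo,great
posemo,awesome
function_words,the
function_words,a
function_words,an
function_words,of
function_words,to
function_words,and
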