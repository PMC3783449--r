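%
1	affect
2	social
3	posemo
4	negemo
%
happy	1	3
glad	1	3
sad	1	4
love	1	3
hate	1	4
excit*	1
friend*	2
family	2
party	2
talk*	2
people	2
great	3
awesome	3
angry	4
depress*	4
sick	4
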