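group,fear,anger,sadness,disgust,anticipation,trust,surprise,joy,total_words
senior contributor,79364,54634,84934,37542,124842,129808,60870,109566,2443022
community guide,18734,12708,19408,8276,36600,39318,18586,34576,754854
community elder,9236,6148,9386,4152,14536,15666,6954,13190,286057
casual contributor,14998,10270,15126,6234,14910,16458,6132,11634,327560
contributor,10186,6706,9796,4372,11760,13108,5038,9626,248629
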