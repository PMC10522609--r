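rno-miR-106b-5p
125a-3p
129-5p
140-5p
142-3p
142-5p
144-3p
148b-5p
155-5p
15b-3p
17-5p
182
183-5p
18a-5p
190b-5p
196c-5p
199a-5p
200b-3p
203a-5p
24-2-5p
26b-3p
27b-5p
29a-5p
29b-3p
301a-3p
3120
31a-3p
31a-5p
32-5p
335
3586-3p
374-3p
452-3p
466c-5p
540-3p
582-3p
582-5p
6327
6334
664-2-5p
664-3p
872-3p
96-5p
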