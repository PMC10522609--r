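rno-miR-139-3p
23a-5p
292-5p
3593-5p
668
711
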