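plant	recovery
BC1-1	86.11
BC1-5	87.03
BC1-6	81.48
BC1-8	83.33
BC1-20	81.48
BC1-27	87.96
BC1-34	85.18
BC1-35	80.55
BC1-36	81.48
BC1-41	86.11
BC1-45	83.33
BC1-46	87.96
BC1-47	85.19
BC1-53	81.48
BC1-54	80.55
BC1-83	81.48
BC1-95	85.18
BC1-101	84.26
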