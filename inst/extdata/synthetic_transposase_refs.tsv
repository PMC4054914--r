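name	p1	p2	p3	class
synthref_DD34E	189	266	301	DD34E
synthref_DD34D	189	266	301	DD34D
synthref_DD35E	188	265	301	DD35E
synthref_DD37D	186	263	301	DD37D
synthref_DD37E	186	263	301	DD37E
synthref_DD39D	184	261	301	DD39D
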