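{"m": 10, "n": 200, "L": 5, "K": 2, "B_in": 1, "boundary": "pinned"}
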