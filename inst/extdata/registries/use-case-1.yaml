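sources:
  icees:
    kind: fixture
    case: 1
    shard: icees
  robokop:
    kind: fixture
    case: 1
    shard: robokop
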