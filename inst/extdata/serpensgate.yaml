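nc: 30
layers:
- from: -1
  'n': 1
  module: Conv
  args:
  - 3
  - 16
  - 3
  - 2
- from: -1
  'n': 1
  module: Conv
  args:
  - 16
  - 32
  - 3
  - 2
- from: -1
  'n': 1
  module: C2f
  args:
  - 32
  - 32
  - yes
- from: -1
  'n': 1
  module: Conv
  args:
  - 32
  - 64
  - 3
  - 2
- from: -1
  'n': 2
  module: C2f
  args:
  - 64
  - 64
  - yes
- from: -1
  'n': 1
  module: Conv
  args:
  - 64
  - 128
  - 3
  - 2
- from: -1
  'n': 2
  module: C2f
  args:
  - 128
  - 128
  - yes
- from: -1
  'n': 1
  module: Conv
  args:
  - 128
  - 256
  - 3
  - 2
- from: -1
  'n': 1
  module: C2f_DySnakeConv
  args:
  - 256
  - 256
  - yes
- from: -1
  'n': 1
  module: SPPELAN
  args:
  - 256
  - 256
  - 1024
- from: -1
  'n': 1
  module: StokenAttention
  args:
  - 256
- from: -1
  'n': 1
  module: Upsample
  args: []
- from:
  - -1
  - 6
  'n': 1
  module: Concat
  args: []
- from: -1
  'n': 1
  module: C2f
  args:
  - 384
  - 128
  - 1
- from: -1
  'n': 1
  module: Upsample
  args: []
- from:
  - -1
  - 4
  'n': 1
  module: Concat
  args: []
- from: -1
  'n': 1
  module: C2f
  args:
  - 192
  - 64
  - 1
- from: -1
  'n': 1
  module: Conv
  args:
  - 64
  - 64
  - 3
  - 2
- from:
  - -1
  - 12
  'n': 1
  module: Concat
  args: []
- from: -1
  'n': 1
  module: C2f
  args:
  - 448
  - 128
  - 1
- from: -1
  'n': 1
  module: Conv
  args:
  - 128
  - 128
  - 3
  - 2
- from:
  - -1
  - 9
  'n': 1
  module: Concat
  args: []
- from: -1
  'n': 1
  module: C2f
  args:
  - 384
  - 256
  - 1
- from:
  - 16
  - 19
  - 22
  'n': 1
  module: Detect
  args:
  - 30
  - - 64
    - 128
    - 256
  - 16
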