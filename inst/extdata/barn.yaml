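# Synthetic single-pen freestall layout (proportions of a 74 x 33 m barn):
# central cubicle/resting band, feeding bands along both long sides, and
# excluded border strips. Vertex coordinates in metres.
bounds: [74, 33]
cubicle_width: 1.25
resting:
  - [[0, 10.5], [74, 10.5], [74, 22.5], [0, 22.5]]
feeding:
  - [[0, 2], [74, 2], [74, 10.5], [0, 10.5]]
  - [[0, 22.5], [74, 22.5], [74, 31], [0, 31]]
excluded:
  - [[0, 0], [74, 0], [74, 2], [0, 2]]
  - [[0, 31], [74, 31], [74, 33], [0, 33]]
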