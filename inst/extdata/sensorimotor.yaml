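# Motor-babbling forward-model learning on a 3-DOF planar arm. This
# experiment uses no brain model: a stateful robot-to-robot controller
# alternates babble (observe, update the incremental least-squares fit on
# the trigonometric tensor basis) and evaluation (held-out pose, TCP
# prediction error to the monitor log).
name: sensorimotor
cle:
  cle_dt: 20
  neural_dt: 1
  seed: 1
world:
  arms:
    arm:
      lengths: [0.4, 0.3, 0.2]
      angles: [0.0, 0.0, 0.0]
      limits_lo: [-1.5708, -1.5708, -1.5708]
      limits_hi: [1.5708, 1.5708, 1.5708]
brain: {}
tfs:
  - builtin: babble
    params: {arm: arm, n_joints: 3, lo: -1.5708, hi: 1.5708}
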