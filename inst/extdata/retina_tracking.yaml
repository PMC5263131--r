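# Retina-based visual tracking: a fixed robot looks at a screen showing a
# moving green circle on a red background. Frames pass through the
# red-green opponency chain; one 320-pixel horizontal stripe of retinal
# current drives layer 1 of the 1,280-neuron readout; layer-2 spike counts
# are decoded to the target centroid, which steers the camera pan joint.
name: retina_tracking
cle:
  cle_dt: 20
  neural_dt: 1
  seed: 1
world:
  background: [40, 40, 40]
  robots:
    icub: {x: 0.0, y: 0.0, theta: 0.0, track: 0.4, fov: 1.5708, res_x: 320, res_y: 17}
  screens:
    screen:
      center: [1.2, 0.0]
      width: 6.0
      height: 0.6
      angle: 1.5708
      color: [255, 0, 0]
      pattern:
        kind: circle
        background: [255, 0, 0]
        fg: [0, 255, 0]
        cx: 0.5
        cy: 0.5
        radius: 0.02
brain:
  builder: retina
  width: 320
  window: 7
  weight: 3.0
tfs:
  - builtin: target_driver
    params: {screen: screen, mode: sine, amp: 0.08, period: 3000}
  - builtin: retina
    params: {robot: icub, row: 9, gain: 6}
  - builtin: centroid
    params: {robot: icub, width: 320, window: 200, floor: 2, fov: 1.5708, k_p: 6, max_vel: 1.5}
  - builtin: truth_monitor
    params: {robot: icub, screen: screen, width: 320, fov: 1.5708}
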