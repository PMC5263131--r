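# Braitenberg vehicle: search counterclockwise until red is seen, then
# approach the red screen. Both screens start blue; a timed event switches
# the right screen to red mid-run.
name: braitenberg
cle:
  cle_dt: 20
  neural_dt: 1
  seed: 1
world:
  background: [128, 128, 128]
  robots:
    husky: {x: 0.0, y: 0.0, theta: 0.0, track: 0.4, fov: 1.5708, res_x: 64, res_y: 64}
  screens:
    screen_left:
      center: [2.2, 1.2]
      width: 2.0
      height: 2.0
      color: [0, 0, 255]
      face: [0.0, 0.0]
    screen_right:
      center: [2.2, -1.2]
      width: 2.0
      height: 2.0
      color: [0, 0, 255]
      face: [0.0, 0.0]
brain:
  populations:
    # low-threshold cells (5 mV above rest) keep each relay stage
    # responsive across the rate range the Poisson inputs produce
    sensors: {size: 3, params: {v_thresh: -65}}
    relays: {size: 3, params: {v_thresh: -65}}
    actors: {size: 2, params: {v_thresh: -65}}
  views:
    sensor_left: {pop: sensors, idx: [1]}
    sensor_right: {pop: sensors, idx: [2]}
    sensor_go: {pop: sensors, idx: [3]}
    actor_left: {pop: actors, idx: [1]}
    actor_right: {pop: actors, idx: [2]}
  projections:
    # each sensor drives its relay; the red sensors also inhibit the go
    # relay, so any detected red silences the search drive
    - pre: sensors
      post: relays
      delay: 1
      weights:
        - [2.0, 0.0, -10.0]
        - [0.0, 2.0, -10.0]
        - [0.0, 0.0, 2.0]
    # crossed excitation: left red ratio drives the right actor and vice
    # versa (turn toward red); the go relay biases the right actor,
    # producing the counterclockwise search
    - pre: relays
      post: actors
      delay: 1
      weights:
        - [0.0, 2.0]
        - [2.0, 0.0]
        - [0.0, 2.0]
events:
  - {at_ms: 6000, action: set_screen_color, args: {id: screen_right, color: [255, 0, 0]}}
tfs:
  - builtin: braitenberg_eye
    params: {robot: husky, r_max: 2000, w_in: 0.6, w_go_in: 0.15}
  - builtin: braitenberg_wheels
    params: {robot: husky, scale: 3, k: 1.0, beta: 0.5, li_tau: 20, li_weight: 1.0}
  - builtin: actor_rates
    params: {window: 200}
  - builtin: pose_monitor
    params: {robot: husky}
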