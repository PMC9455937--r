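{
  "joint_names": ["hip_l", "knee_l", "ankle_l", "hip_r", "knee_r", "ankle_r"],
  "parent_index": [0, 1, 2, 1, 4, 5],
  "bone_lengths": [null, 42, 40, 22, 42, 40],
  "quadrant": ["lower-left", "lower-left", "lower-left", "lower-right", "lower-right", "lower-right"],
  "hip_left": 1,
  "hip_right": 4,
  "hip_center": null,
  "phantom_index": null,
  "gait_joints": {
    "hip_l": 1,
    "knee_l": 2,
    "ankle_l": 3,
    "hip_r": 4,
    "knee_r": 5,
    "ankle_r": 6
  },
  "fps_default": 60
}
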