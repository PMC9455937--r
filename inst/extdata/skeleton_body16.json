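{
  "joint_names": ["head", "neck", "shoulder_l", "elbow_l", "wrist_l", "shoulder_r", "elbow_r", "wrist_r", "hip_l", "knee_l", "ankle_l", "toe_l", "hip_r", "knee_r", "ankle_r", "toe_r"],
  "parent_index": [2, 0, 2, 3, 4, 2, 6, 7, 2, 9, 10, 11, 2, 13, 14, 15],
  "bone_lengths": [12, null, 23.6008474424119, 30, 26, 23.6008474424119, 30, 26, 42.4499705535822, 42, 40, 15, 42.4499705535822, 42, 40, 15],
  "quadrant": ["axial", "axial", "upper-left", "upper-left", "upper-left", "upper-right", "upper-right", "upper-right", "lower-left", "lower-left", "lower-left", "lower-left", "lower-right", "lower-right", "lower-right", "lower-right"],
  "hip_left": 9,
  "hip_right": 13,
  "hip_center": null,
  "phantom_index": null,
  "gait_joints": {
    "hip_l": 9,
    "knee_l": 10,
    "ankle_l": 11,
    "hip_r": 13,
    "knee_r": 14,
    "ankle_r": 15
  },
  "fps_default": 60
}
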