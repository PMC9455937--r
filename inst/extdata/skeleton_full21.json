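{
  "joint_names": ["pelvis", "hip_l", "knee_l", "ankle_l", "toe_l", "hip_r", "knee_r", "ankle_r", "toe_r", "spine", "chest", "neck", "head", "shoulder_l", "elbow_l", "wrist_l", "hand_l", "shoulder_r", "elbow_r", "wrist_r", "hand_r"],
  "parent_index": [0, 1, 2, 3, 4, 1, 6, 7, 8, 1, 10, 11, 12, 11, 14, 15, 16, 11, 18, 19, 20],
  "bone_lengths": [null, 11, 42, 40, 15, 11, 42, 40, 15, 12, 15, 14, 12, 19, 30, 26, 10, 19, 30, 26, 10],
  "quadrant": ["axial", "lower-left", "lower-left", "lower-left", "lower-left", "lower-right", "lower-right", "lower-right", "lower-right", "axial", "axial", "axial", "axial", "upper-left", "upper-left", "upper-left", "upper-left", "upper-right", "upper-right", "upper-right", "upper-right"],
  "hip_left": 2,
  "hip_right": 6,
  "hip_center": 1,
  "phantom_index": null,
  "gait_joints": {
    "hip_l": 2,
    "knee_l": 3,
    "ankle_l": 4,
    "hip_r": 6,
    "knee_r": 7,
    "ankle_r": 8
  },
  "fps_default": 60
}
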