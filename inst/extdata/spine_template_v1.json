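{
  "asset": "ucspine canonical C0-C3 template geometry",
  "version": "1.0",
  "units": "mm",
  "coordinate_convention": {
    "x": "anterior",
    "y": "left (medio-lateral)",
    "z": "cranial",
    "flexion": "positive rotation of the upper body about +y relative to the lower",
    "note": "Right-handed frame with the foramen magnum horizontal in neutral. Absolute coordinates are a canonical anatomically plausible choice; only length changes enter the ligament stress tables."
  },
  "sagittal_axis": [0, 1, 0],
  "joint_centers_world": {
    "C0C1": [0, 0, 52],
    "C1C2": [0, 0, 35],
    "C2C3": [0, 0, 15]
  },
  "vertebrae": {
    "C0": {
      "origin_world": [0, 0, 52],
      "markers": {
        "post_foramen": [-40, 0, 6],
        "foramen_left": [-25, 30, 8],
        "foramen_right": [-25, -30, 8],
        "occ_crest": [-52, 0, 22]
      },
      "attachments": {
        "apical_site": [5, 0, 4],
        "alar_site": [10, 0, 3],
        "cruciate_site": [-2, 0, 3],
        "occ_collateral_site": [2, 25, 2],
        "capsular_left": [10, 22, 1],
        "capsular_right": [10, -22, 1]
      }
    },
    "C1": {
      "origin_world": [0, 0, 35],
      "markers": {
        "post_tubercle": [-38, 0, 5],
        "transverse_left": [0, 40, 3],
        "transverse_right": [0, -40, 3],
        "post_arch": [-22, 0, 12]
      },
      "attachments": {
        "transverse_left": [0, 40, 3],
        "transverse_right": [0, -40, 3],
        "post_tubercle": [-38, 0, 5],
        "flavum_inferior": [-30, 0, 2],
        "aa_collateral_site": [5, 25, 1],
        "occ_collateral_site": [2, 25, 5],
        "capsular_c0c1_left": [10, 22, 7],
        "capsular_c0c1_right": [10, -22, 7],
        "capsular_c1c2_left": [8, 20, 1],
        "capsular_c1c2_right": [8, -20, 1],
        "all_superior": [20, 0, 3]
      }
    },
    "C2": {
      "origin_world": [0, 0, 15],
      "markers": {
        "spinous": [-42, 0, -2],
        "transverse_left": [0, 32, 2],
        "transverse_right": [0, -32, 2],
        "lamina": [-26, 0, 8]
      },
      "attachments": {
        "dens_tip": [5, 0, 32],
        "dens_posterior": [-2, 0, 29],
        "transverse_left": [0, 32, 2],
        "transverse_right": [0, -32, 2],
        "spinous": [-42, 0, -2],
        "spinous_tip": [-46, 0, -2],
        "flavum_superior": [-32, 0, 5],
        "flavum_inferior": [-32, 0, 1],
        "aa_collateral_site": [5, 25, 3],
        "capsular_c1c2_left": [8, 20, 5],
        "capsular_c1c2_right": [8, -20, 5],
        "capsular_c2c3_left": [-5, 18, 1],
        "capsular_c2c3_right": [-5, -18, 1],
        "all_inferior": [18, 0, 5],
        "pll_superior": [-8, 0, 3]
      }
    },
    "C3": {
      "origin_world": [0, 0, 0],
      "markers": {
        "spinous": [-35, 0, -8],
        "transverse_left": [0, 30, -5],
        "transverse_right": [0, -30, -5],
        "body_post": [-18, 0, 2]
      },
      "attachments": {
        "transverse_left": [0, 30, -5],
        "transverse_right": [0, -30, -5],
        "spinous": [-35, 0, -8],
        "spinous_tip": [-39, 0, -8],
        "flavum_superior": [-28, 0, -2],
        "capsular_left": [-5, 18, -2],
        "capsular_right": [-5, -18, -2],
        "pll_inferior": [-8, 0, -2]
      }
    }
  }
}
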