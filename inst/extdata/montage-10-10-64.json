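{
  "montage": ["10-10-64"],
  "head_radius": [1],
  "electrodes": {
    "label": ["Fp1", "Fpz", "Fp2", "AF7", "AF3", "AFz", "AF4", "AF8", "F7", "F5", "F3", "F1", "Fz", "F2", "F4", "F6", "F8", "FT9", "FT7", "FC5", "FC3", "FC1", "FCz", "FC2", "FC4", "FC6", "FT8", "FT10", "T7", "C5", "C3", "C1", "Cz", "C2", "C4", "C6", "T8", "TP7", "CP5", "CP3", "CP1", "CPz", "CP2", "CP4", "CP6", "TP8", "P7", "P5", "P3", "P1", "Pz", "P2", "P4", "P6", "P8", "PO7", "PO3", "POz", "PO4", "PO8", "O1", "Oz", "O2", "Iz"],
    "x": [-0.1396, 0, 0.1396, -0.6917, -0.3459, 0, 0.3459, 0.6917, -0.7838, -0.5879, -0.3919, -0.196, 0, 0.196, 0.3919, 0.5879, 0.7838, -1.0712, -0.857, -0.6427, -0.4285, -0.2142, 0, 0.2142, 0.4285, 0.6427, 0.857, 1.0712, -0.88, -0.66, -0.44, -0.22, 0, 0.22, 0.44, 0.66, 0.88, -0.857, -0.6427, -0.4285, -0.2142, 0, 0.2142, 0.4285, 0.6427, 0.857, -0.7838, -0.5879, -0.3919, -0.196, 0, 0.196, 0.3919, 0.5879, 0.7838, -0.6917, -0.3459, 0, 0.3459, 0.6917, -0.1396, 0, 0.1396, 0],
    "y": [0.85, 0.85, 0.85, 0.68, 0.68, 0.68, 0.68, 0.68, 0.5, 0.5, 0.5, 0.5, 0.5, 0.5, 0.5, 0.5, 0.5, 0.25, 0.25, 0.25, 0.25, 0.25, 0.25, 0.25, 0.25, 0.25, 0.25, 0.25, 0, 0, 0, 0, 0, 0, 0, 0, 0, -0.25, -0.25, -0.25, -0.25, -0.25, -0.25, -0.25, -0.25, -0.25, -0.5, -0.5, -0.5, -0.5, -0.5, -0.5, -0.5, -0.5, -0.5, -0.68, -0.68, -0.68, -0.68, -0.68, -0.85, -0.85, -0.85, -1],
    "hemisphere": ["left", "midline", "right", "left", "left", "midline", "right", "right", "left", "left", "left", "left", "midline", "right", "right", "right", "right", "left", "left", "left", "left", "left", "midline", "right", "right", "right", "right", "right", "left", "left", "left", "left", "midline", "right", "right", "right", "right", "left", "left", "left", "left", "midline", "right", "right", "right", "right", "left", "left", "left", "left", "midline", "right", "right", "right", "right", "left", "left", "midline", "right", "right", "left", "midline", "right", "midline"]
  }
}
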