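# BOILED-Egg ellipse geometry in (tPSA, WLogP) space.
#
# Parameters transcribed from the published best-fit ellipses of the
# BOILED-Egg model (Daina & Zoete 2016, ChemMedChem 11:1117-1121): the
# "white" region predicts high human intestinal absorption (Fa >= 0.30),
# the "yolk" region blood-brain-barrier permeation (LogBB >= 0).
#
# Geometry convention: center (tpsa, wlogp) in data units; semi-axes are
# half the published full axis lengths; rotation in degrees, applied in
# data units (tPSA on the abscissa, WLogP on the ordinate); boundary points
# count as inside.
version: 1
boundary_inclusive: true
ellipses:
  intestinal:
    interpretation: "Fa >= 0.30"
    center_tpsa: 71.051
    center_wlogp: 2.292
    semi_axis_tpsa: 71.0405
    semi_axis_wlogp: 4.3700
    rotation_deg: -1.031325
  brain:
    interpretation: "LogBB >= 0"
    center_tpsa: 38.117
    center_wlogp: 3.177
    semi_axis_tpsa: 41.0305
    semi_axis_wlogp: 2.7785
    rotation_deg: -0.171887
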