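# Plate geometry. Indices in code are 0-based; display strings use 1-based
# columns. Additional plate kinds can be added here without code changes.
crystal:
  rows: 8          # displayed A-H
  cols: 12         # displayed 1-12
  drops: 3         # subwell drops, displayed a-c
  # maximum in-drop dispense offset from the drop centre, mm
  drop_half_extent_mm: 1.5
  # centre of each subwell drop relative to the 96-well footprint centre, mm.
  # The transfer-list writer adds these to the user's in-drop offset so the
  # destination well column can stay a plain 96-well address.
  drop_centre_offset_mm:
    a: [-1.9, -1.9]
    b: [1.9, -1.9]
    c: [1.9, 1.9]
library:
  "384":
    rows: 16       # A-P
    cols: 24
  "1536":
    rows: 32       # A-Z then AA-AF
    cols: 48
# acoustic droplet ejection quantum, nL: every transfer volume must be an
# exact multiple of this
droplet_quantum_nl: 2.5
# pins per cryo puck (SPINE/Unipuck convention)
puck_pins: 16
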