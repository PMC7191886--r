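# Group taxonomy for inhalable/respirable dust conversion.
#
# The activity lists are seeded with every activity string printed in the
# source tables and group definitions; the full code list of the underlying
# exposure database is not public, so users may extend these lists for
# their own exports. Matching is case-insensitive on trimmed strings; any
# activity not listed falls back to group 6 ("others").
#
# Note: the source says twelve material subcategories are formed before
# pooling, but only ten are printed with their group membership; the ten
# printed ones are listed here. Wood is deliberately NOT mapped to the
# mineral-dominated group A (wood dust is predominantly inhalable and not
# comparable to mineral dust); it stays unclassified, as do unknown
# materials.

activity_groups:
  "1":
    name: surface treatment
    activities:
      - glazing
      - spray painting
      - powder coating
      - galvanization
      - treatment and post-treatment blasting
      - fettling shop, abrasive blasting, silica sand abrasive, workpiece sand-coated, room
      - abrasive blasting systems, dry, open
      - sandblasting
  "2":
    name: high temperature processing
    activities:
      - thermal cutting
      - extrusion
      - soft soldering
      - soft soldering, flame soldering
      - hard soldering, flame soldering
      - arc soldering
      - mig soldering
      - hot-chamber die-casting machine or plant
      - cold-chamber die-casting machine or plant
      - continuous casting machine or plant
      - manual arc welding with coated rod electrode
      - manual arc welding without coated rod electrode
      - metal inert gas welding
      - metal active gas welding
      - tungsten inert gas welding
      - arc welding, mixed arc process
      - plasma welding
      - laser welding
      - resistance spot welding
      - metal welding, mixed welding processes
      - flame cutting
      - plasma cutting
      - laser cutting
      - wire drawing
  "3":
    name: filling/transport/storage
    activities:
      - filling
      - transport
      - storage
      - loading
      - bagging
  "4":
    name: machining/abrasive techniques
    activities:
      - grinding
      - milling
      - sawing
      - drilling
      - polishing
      - chiseling, manually
      - chiseling, mechanically
      - embossing, manually
      - embossing, mechanically
  "5":
    name: forming
    activities:
      - roll forming
      - pressing
      - bending
  "6":
    name: others
    activities: []

material_groups:
  A:
    name: mineral-dominated
    subcategories:
      - {code: synthetic material/rubber/epoxy resin/powder coating, n: 799}
      - {code: mineral material/glass/plaster/gypsum/concrete/carbon/graphite, n: 7576}
      - {code: others (mineral), n: 940}
  B:
    name: metal-dominated
    subcategories:
      - {code: metal/metal ores/slag/metallic shot, n: 5069}
      - {code: lacquers/paint, n: 108}
      - {code: electronic waste, n: 92}
  C:
    name: fiber-dominated
    subcategories:
      - {code: textile, n: 101}
      - {code: mineral fibers/ceramic fibers, n: 197}
      - {code: paper, n: 126}
      - {code: asphalt/bitumen, n: 112}

# Only these four activity-by-material combinations have published
# conversion functions of their own.
combined_groups: ["1-A", "2-B", "4-A", "6-B"]

# Heuristic groups: trial-and-error refined activity subsets with the best
# fit quality. "material" is the material-group requirement for membership:
# metal -> group B, mineral -> group A, all -> any classified material.
#
# NOTE on zeta: the source table prints originating group "4-A" while the
# accompanying text calls chiseling a subgroup of "5-A"; the table value is
# recorded here and the contradiction flagged.
heuristic_groups:
  alpha:
    name: soldering
    originating_group: 2-B
    material: metal
    activities:
      - soft soldering
      - soft soldering, flame soldering
      - hard soldering, flame soldering
      - arc soldering
      - mig soldering
  beta:
    name: casting (metalworking)
    originating_group: 2-B
    material: metal
    activities:
      - hot-chamber die-casting machine or plant
      - cold-chamber die-casting machine or plant
      - continuous casting machine or plant
  gamma:
    name: welding
    originating_group: 2-B
    material: metal
    activities:
      - manual arc welding with coated rod electrode
      - manual arc welding without coated rod electrode
      - metal inert gas welding
      - metal active gas welding
      - tungsten inert gas welding
      - arc welding, mixed arc process
      - plasma welding
      - laser welding
      - resistance spot welding
      - metal welding, mixed welding processes
  delta:
    name: high temperature cutting
    originating_group: 2-B
    material: metal
    activities:
      - flame cutting
      - plasma cutting
      - laser cutting
  epsilon:
    name: blasting
    originating_group: "1"
    material: all
    activities:
      - treatment and post-treatment blasting
      - fettling shop, abrasive blasting, silica sand abrasive, workpiece sand-coated, room
      - abrasive blasting systems, dry, open
      - sandblasting
  zeta:
    name: chiseling, embossing
    originating_group: 4-A
    material: mineral
    activities:
      - chiseling, manually
      - chiseling, mechanically
      - embossing, manually
      - embossing, mechanically
  eta:
    name: wire drawing
    originating_group: 2-B
    material: metal
    activities:
      - wire drawing
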