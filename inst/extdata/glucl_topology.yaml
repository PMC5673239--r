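# Receptor topology for GluCl (crystal numbering as in PDB 3RIF / 4TNV).
#
# NOTE ON PROVENANCE: the anchor residues (9' = Leu254, M2-M3 proline 268,
# beta1-beta2 tip Val45, the binding-site pairs, the M2/M3 separation
# segments 258-265 / 274-280) are established landmarks of this receptor.
# The EC/TM domain boundaries and the M1-M4 helix intervals are CURATED
# values (ECD = N-terminus up to the residue preceding M1, TMD = M1-M4),
# not literature-tabulated ones; adjust them if your model differs.
chains: [A, B, C, D, E]
ec_range: [2, 215]
tm_range: [216, 436]
m_ranges:
  M1: [216, 241]
  M2: [243, 266]
  M3: [270, 295]
  M4: [404, 432]
# M2 prime map: prime index n' corresponds to residue 245 + n
prime_map:
  "-2": 243
  "2": 247
  "9": 254
  "13": 258
key_residues:
  pore_9prime: 254
  M2M3_proline: 268
  beta12_tip: 45
  orthosteric_plus: 150     # Ser150 (+)
  orthosteric_minus: 56     # Arg56 (-)
  allosteric_plus: 281      # Gly281 (+)
  allosteric_minus: 218     # Leu218 (-)
  beta_expansion_a: 211     # Arg211
  beta_expansion_b: 44      # Val44
  aromatic_1: 151           # Tyr151
  aromatic_2: 200           # Tyr200
interface_order: [A, B, C, D, E]
segments:
  m2_sep: [258, 265]
  m3_sep: [274, 280]
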