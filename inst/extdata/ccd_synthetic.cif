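# Synthetic chemical component dictionary for the bundled test fixtures.
# Layout follows the chem_comp_atom / chem_comp_bond loop structure of the
# wwPDB Chemical Component Dictionary; the components are synthetic.
data_XBZ
loop_
_chem_comp_atom.comp_id
_chem_comp_atom.atom_id
_chem_comp_atom.type_symbol
_chem_comp_atom.charge
_chem_comp_atom.pdbx_aromatic_flag
XBZ C1 C 0 Y
XBZ C2 C 0 Y
XBZ C3 C 0 Y
XBZ C4 C 0 Y
XBZ C5 C 0 Y
XBZ C6 C 0 Y
loop_
_chem_comp_bond.comp_id
_chem_comp_bond.atom_id_1
_chem_comp_bond.atom_id_2
_chem_comp_bond.value_order
_chem_comp_bond.pdbx_aromatic_flag
XBZ C1 C2 AROM Y
XBZ C2 C3 AROM Y
XBZ C3 C4 AROM Y
XBZ C4 C5 AROM Y
XBZ C5 C6 AROM Y
XBZ C6 C1 AROM Y
data_XAC
loop_
_chem_comp_atom.comp_id
_chem_comp_atom.atom_id
_chem_comp_atom.type_symbol
_chem_comp_atom.charge
_chem_comp_atom.pdbx_aromatic_flag
XAC C1 C 0 N
XAC C2 C 0 N
XAC O1 O 0 N
XAC O2 O -1 N
loop_
_chem_comp_bond.comp_id
_chem_comp_bond.atom_id_1
_chem_comp_bond.atom_id_2
_chem_comp_bond.value_order
_chem_comp_bond.pdbx_aromatic_flag
XAC C1 C2 SING N
XAC C2 O1 DOUB N
XAC C2 O2 SING N
data_HOH
loop_
_chem_comp_atom.comp_id
_chem_comp_atom.atom_id
_chem_comp_atom.type_symbol
_chem_comp_atom.charge
_chem_comp_atom.pdbx_aromatic_flag
HOH O O 0 N
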