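data_camin2_optimized
_cell_length_a     19.27
_cell_length_b     9.74
_cell_length_c     17.05
_cell_angle_alpha  90
_cell_angle_beta   107.99
_cell_angle_gamma  90
_symmetry_space_group_name_H-M  'C 2/c'
loop_
_symmetry_equiv_pos_as_xyz
'x, y, z'
'-x, y, 1/2-z'
'-x, -y, -z'
'x, -y, 1/2+z'
loop_
_atom_site_label
_atom_site_type_symbol
_atom_site_fract_x
_atom_site_fract_y
_atom_site_fract_z
Ca1 Ca 0.0000 0.1250 0.2500
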