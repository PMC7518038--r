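{"core_atoms":[0,1,2,3,4,5,6,7,8,9,10,11,12],"attachments":[{"position":"R6","core_atom":1,"replaced_hydrogen":13},{"position":"R7","core_atom":2,"replaced_hydrogen":14},{"position":"R8","core_atom":3,"replaced_hydrogen":15},{"position":"R3p","core_atom":4,"replaced_hydrogen":16},{"position":"R4p","core_atom":8,"replaced_hydrogen":17}]}
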