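# Generalized Karplus coefficient registry.
#
# proton_proton: coefficient sets of the empirical generalized (substituent-
# corrected) Karplus parameterisation for vicinal H-C-C-H couplings,
#   J(theta) = P1 cos^2(theta) + P2 cos(theta) + P3
#              + sum_i dchi_i [P4 + P5 cos^2(xi_i theta + P6 |dchi_i|)],
# keyed by the number of non-hydrogen substituents on the two carbons.
#
# group_electronegativity: group electronegativity differences (Huggins
# scale) relative to hydrogen; OR = ether/glycosidic oxygen, OH = hydroxyl
# oxygen, NC = amide nitrogen, CC = carbon substituent.
#
# amide: three-coefficient Karplus form A cos^2(theta) + B cos(theta) + C for
# the acetamido 3J(HN,H2) coupling over the H2-C2-N-HN dihedral. Edit these
# to match your preferred literature parameterisation.
proton_proton:
  disubstituted:
    P1: 13.89
    P2: -0.98
    P3: 0.0
    P4: 1.02
    P5: -3.40
    P6: 14.9
  trisubstituted:
    P1: 13.22
    P2: -0.99
    P3: 0.0
    P4: 0.87
    P5: -2.46
    P6: 19.9
  tetrasubstituted:
    P1: 13.24
    P2: -0.91
    P3: 0.0
    P4: 0.53
    P5: -2.41
    P6: 15.5
group_electronegativity:
  OR: 1.27
  OH: 1.26
  NC: 0.85
  CC: 0.45
amide:
  A: 9.5
  B: -1.4
  C: 0.3
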