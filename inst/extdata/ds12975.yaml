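# Kinetic parameters, P. chrysogenum strain DS12975.
# Units: qs_max mol_s/Cmol_x/s; Ks, Kp mol_s/kg; beta mol_p/Cmol_x/h;
# KdE 1/h; Ysx Cmol_x/mol_s; Ysp mol_p/mol_s; ms mol_s/Cmol_x/h;
# Cx Cmol_x/kg; mu_floor 1/h.
qs_max: 12.47e-6
Ks: 7.8e-6
beta: 6.77e-4
Kp: 7.4e-6
KdE: 5.0e-3
Ysx: 4.5
Ysp: 0.9
ms: 2.65e-3
Cx: 1.96
mu_floor: 0.0
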