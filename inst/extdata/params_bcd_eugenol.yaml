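# Synthetic parameter table for the packaged beta-cyclodextrin / eugenol
# conformers (SYBYL atom types as written by the mol2 generator).
#
# Lennard-Jones values are standard AMBER-class element parameters given
# as like-pair well depth epsilon (kcal/mol) and like-pair minimum
# distance rmin (A); the 12-10 hydrogen-bond pair uses the classic
# C/D coefficients for O-H...O contacts.  Bond and angle equilibria are
# the mean values observed in the packaged eugenol conformer (the guest
# is treated rigidly, so these terms contribute only a small constant
# strain); the wildcard torsion term is zero.  This table is a synthetic,
# self-consistent stand-in, not a literature parameter set.
atom_types:
  C.3:  {epsilon: 0.1094, rmin: 3.816}
  C.2:  {epsilon: 0.0860, rmin: 3.816}
  C.ar: {epsilon: 0.0860, rmin: 3.816}
  O.3:  {epsilon: 0.2104, rmin: 3.3224}
  H:    {epsilon: 0.0157, rmin: 2.9740}
hbond_pairs:
  - {donor: H, acceptor: O.3, C: 7557.0, D: 2385.0}
bonds:
  - {types: [C.2, C.2],  kr: 549.0, req: 1.3396}
  - {types: [C.2, C.3],  kr: 317.0, req: 1.5026}
  - {types: [C.2, H],    kr: 340.0, req: 1.0865}
  - {types: [C.3, C.ar], kr: 317.0, req: 1.5113}
  - {types: [C.3, H],    kr: 340.0, req: 1.0958}
  - {types: [C.3, O.3],  kr: 320.0, req: 1.4198}
  - {types: [C.ar, C.ar], kr: 469.0, req: 1.3996}
  - {types: [C.ar, H],   kr: 367.0, req: 1.0862}
  - {types: [C.ar, O.3], kr: 450.0, req: 1.3703}
  - {types: [H, O.3],    kr: 553.0, req: 0.9689}
angles:
  - {types: [C.2, C.2, C.3], ktheta: 63.0, theta_eq: 124.39}
  - {types: [C.2, C.2, H],   ktheta: 50.0, theta_eq: 120.47}
  - {types: [C.2, C.3, C.ar], ktheta: 63.0, theta_eq: 112.29}
  - {types: [C.2, C.3, H],   ktheta: 50.0, theta_eq: 109.97}
  - {types: [C.3, C.2, H],   ktheta: 50.0, theta_eq: 116.69}
  - {types: [C.3, C.ar, C.ar], ktheta: 70.0, theta_eq: 120.38}
  - {types: [C.3, O.3, C.ar], ktheta: 60.0, theta_eq: 117.41}
  - {types: [C.ar, C.3, H], ktheta: 50.0, theta_eq: 109.33}
  - {types: [C.ar, C.ar, C.ar], ktheta: 63.0, theta_eq: 120.0}
  - {types: [C.ar, C.ar, H], ktheta: 50.0, theta_eq: 119.84}
  - {types: [C.ar, C.ar, O.3], ktheta: 70.0, theta_eq: 120.05}
  - {types: [C.ar, O.3, H], ktheta: 35.0, theta_eq: 109.01}
  - {types: [H, C.2, H], ktheta: 35.0, theta_eq: 117.51}
  - {types: [H, C.3, H], ktheta: 35.0, theta_eq: 108.06}
  - {types: [H, C.3, O.3], ktheta: 50.0, theta_eq: 110.05}
torsions:
  - {types: [X, X, X, X], terms: [{Vn: 0.0, n: 1, gamma: 0.0}]}
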