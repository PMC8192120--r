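states:
- name: ToCl
  conformation: outward
  ligands:
    Cl: 1
- name: ToClNa
  conformation: outward
  ligands:
    Cl: 1
    Na: 1
- name: ToClNaS
  conformation: outward
  ligands:
    Cl: 1
    Na: 1
    S: 1
- name: TiClNaS
  conformation: inward
  ligands:
    Cl: 1
    Na: 1
    S: 1
- name: TiClS
  conformation: inward
  ligands:
    Cl: 1
    S: 1
- name: TiCl
  conformation: inward
  ligands:
    Cl: 1
- name: TiClK
  conformation: inward
  ligands:
    Cl: 1
    K: 1
- name: ToClK
  conformation: outward
  ligands:
    Cl: 1
    K: 1
- name: TiClNa
  conformation: inward
  ligands:
    Cl: 1
    Na: 1
- name: TiClH
  conformation: inward
  ligands:
    Cl: 1
    H: 1
- name: ToClH
  conformation: outward
  ligands:
    Cl: 1
    H: 1
- name: TiClLi
  conformation: inward
  ligands:
    Cl: 1
    Li: 1
- name: Tcond
  conformation: conducting
  ligands:
    Cl: 1
    K: 1
transitions:
- from: ToCl
  to: ToClNa
  kf0: 1000000.0
  kr0: 15000.0
  zQ: 0.0
  lig_f: Na
  side_f: out
- from: ToClNa
  to: ToClNaS
  kf0: 100000.0
  kr0: 1.0
  zQ: 0.3983
  lig_f: S
  side_f: out
- from: ToClNaS
  to: TiClNaS
  kf0: 600.0
  kr0: 300.0
  zQ: 0.0
- from: TiClNaS
  to: TiClS
  kf0: 1000.0
  kr0: 20000.0
  zQ: 0.4517
  lig_r: Na
  side_r: in
- from: TiClS
  to: TiCl
  kf0: 1.0
  kr0: 100000.0
  zQ: 0.15
  lig_r: S
  side_r: in
- from: TiCl
  to: ToCl
  kf0: 0.05
  kr0: 0.333333333333333
  zQ: 1.0
- from: TiCl
  to: TiClK
  kf0: 10000.0
  kr0: 300.0
  zQ: -0.4517
  lig_f: K
  side_f: in
- from: TiClK
  to: ToClK
  kf0: 1.958
  kr0: 2.5
  zQ: 0.0
- from: ToClK
  to: ToCl
  kf0: 10000.0
  kr0: 1740444.444444444961846
  zQ: -0.5483
  lig_r: K
  side_r: out
- from: TiCl
  to: TiClNa
  kf0: 1000.0
  kr0: 1000.0
  zQ: -0.4517
  lig_f: Na
  side_f: in
- from: TiClNa
  to: ToClNa
  kf0: 25.0
  kr0: 2.5
  zQ: 0.0
- from: TiCl
  to: TiClH
  kf0: 10000000000.0
  kr0: 1000.0
  zQ: -0.4517
  lig_f: H
  side_f: in
- from: TiClH
  to: ToClH
  kf0: 2.2895
  kr0: 130.0
  zQ: 0.0
- from: ToClH
  to: ToCl
  kf0: 10000.0
  kr0: 11741025641.025642395019531
  zQ: -0.5483
  lig_r: H
  side_r: out
- from: TiCl
  to: TiClLi
  kf0: 10000.0
  kr0: 1000.0
  zQ: -0.4517
  lig_f: Li
  side_f: in
- from: TiClK
  to: Tcond
  kf0: 0.05
  kr0: 10000.0
  zQ: 0.0
meta:
  transporter: SERT
  substrate_bound_in: TiClS
  substrate_free_in: TiCl
  substrate_koff_in: 1.0
  substrate_kon_in: 100000.0
  conducting_state: Tcond
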