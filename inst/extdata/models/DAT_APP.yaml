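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
- name: ToccClNaS
  conformation: occluded
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
- name: ToccClK
  conformation: occluded
  ligands:
    Cl: 1
    K: 1
- name: ToccCl
  conformation: occluded
  ligands:
    Cl: 1
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
  zQ: 0.1
  lig_f: Na
  side_f: out
- from: ToClNa
  to: ToClNaS
  kf0: 900000.0
  kr0: 30.0
  zQ: 0.05
  lig_f: S
  side_f: out
- from: ToClNaS
  to: ToccClNaS
  kf0: 300.0
  kr0: 2400.0
  zQ: 0.1661
- from: ToccClNaS
  to: TiClNaS
  kf0: 1.8107
  kr0: 0.90535
  zQ: 0.0
- from: TiClNaS
  to: TiClS
  kf0: 1000.0
  kr0: 10000.0
  zQ: 0.25
  lig_r: Na
  side_r: in
- from: TiClS
  to: TiCl
  kf0: 30.0
  kr0: 900000.0
  zQ: 0.1
  lig_r: S
  side_r: in
- from: TiCl
  to: ToccCl
  kf0: 4.7181
  kr0: 10.0
  zQ: 0.0
- from: TiCl
  to: TiClK
  kf0: 10000.0
  kr0: 3000.0
  zQ: -0.25
  lig_f: K
  side_f: in
- from: TiClK
  to: ToccClK
  kf0: 2.6615
  kr0: 5.0
  zQ: 0.0
- from: ToccClK
  to: ToccCl
  kf0: 5000.0
  kr0: 18803.473149502275191
  zQ: 0.25
  lig_r: K
  side_r: in
- from: ToccCl
  to: ToCl
  kf0: 40.0
  kr0: 31.454000000000001
  zQ: 1.0
- from: TiClK
  to: Tcond
  kf0: 0.07
  kr0: 10000.0
  zQ: 0.0
meta:
  transporter: DAT
  substrate_bound_in: TiClS
  substrate_free_in: TiCl
  substrate_koff_in: 30.0
  substrate_kon_in: 900000.0
  conducting_state: Tcond
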