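- name: physiological
  inside:
    Na: 0.006
    K: 0.163
    Cl: 0.006
    H: 6.309573444802e-08
    Li: 0.0
    S: 0.0
  outside:
    Na: 0.163
    K: 0.0
    Cl: 0.163
    H: 3.981071705535e-08
    Li: 0.0
    S: 0.0
- name: NMDG_in
  inside:
    Na: 0.0
    K: 0.0
    Cl: 0.163
    H: 6.309573444802e-08
    Li: 0.0
    S: 0.0
  outside:
    Na: 0.163
    K: 0.0
    Cl: 0.163
    H: 3.981071705535e-08
    Li: 0.0
    S: 0.0
- name: high_Na_in
  inside:
    Na: 0.163
    K: 0.0
    Cl: 0.163
    H: 6.309573444802e-08
    Li: 0.0
    S: 0.0
  outside:
    Na: 0.163
    K: 0.0
    Cl: 0.163
    H: 3.981071705535e-08
    Li: 0.0
    S: 0.0
- name: high_Li_in
  inside:
    Na: 0.006
    K: 0.0
    Cl: 0.136
    H: 6.309573444802e-08
    Li: 0.163
    S: 0.0
  outside:
    Na: 0.163
    K: 0.0
    Cl: 0.163
    H: 3.981071705535e-08
    Li: 0.0
    S: 0.0
- name: pH5.6_in
  inside:
    Na: 0.0
    K: 0.0
    Cl: 0.141
    H: 2.51188643151e-06
    Li: 0.0
    S: 0.0
  outside:
    Na: 0.163
    K: 0.0
    Cl: 0.163
    H: 3.981071705535e-08
    Li: 0.0
    S: 0.0
- name: control_external
  inside:
    Na: 0.0
    K: 0.0
    Cl: 0.0
    H: 6.309573444802e-08
    Li: 0.0
    S: 0.0
  outside:
    Na: 0.163
    K: 0.0
    Cl: 0.163
    H: 3.981071705535e-08
    Li: 0.0
    S: 0.0
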