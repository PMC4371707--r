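L_arm: 0.3
L_farm: 0.35
m_arm: 2.1
m_farm: 1.65
r_arm: 0.04
r_farm: 0.03
eps_inertia: 5.0e-05
delta_min: 0.0
delta_max: 2.9
K_limit: 30.0
b_limit: 2.0
gravity_g: 9.81
muscles:
- name: shoulder_flexor
  origin:
  - 0.02
  - 0.09
  - 0.01
  origin_frame: 0
  insertion:
  - 0.0
  - 0.035
  - -0.12
  insertion_frame: 1
  bend:
    enabled: no
    a:
    - 0.0
    - 0.0
    - 0.0
    b:
    - 0.0
    - 0.0
    - 0.0
    normal:
    - 0.0
    - 0.0
    - 1.0
    frame: 1
  F_max: 600.0
  tau_act: 0.02
  k_passive: 50.0
  b_passive: 20.0
  v_max: 0.6
- name: shoulder_extensor
  origin:
  - -0.02
  - -0.09
  - 0.01
  origin_frame: 0
  insertion:
  - 0.0
  - -0.035
  - -0.12
  insertion_frame: 1
  bend:
    enabled: no
    a:
    - 0.0
    - 0.0
    - 0.0
    b:
    - 0.0
    - 0.0
    - 0.0
    normal:
    - 0.0
    - 0.0
    - 1.0
    frame: 1
  F_max: 600.0
  tau_act: 0.02
  k_passive: 50.0
  b_passive: 20.0
  v_max: 0.6
- name: abductor
  origin:
  - 0.1
  - 0.0
  - 0.04
  origin_frame: 0
  insertion:
  - 0.035
  - 0.0
  - -0.13
  insertion_frame: 1
  bend:
    enabled: no
    a:
    - 0.0
    - 0.0
    - 0.0
    b:
    - 0.0
    - 0.0
    - 0.0
    normal:
    - 0.0
    - 0.0
    - 1.0
    frame: 1
  F_max: 600.0
  tau_act: 0.02
  k_passive: 50.0
  b_passive: 20.0
  v_max: 0.6
- name: adductor
  origin:
  - -0.09
  - 0.02
  - -0.04
  origin_frame: 0
  insertion:
  - -0.035
  - 0.0
  - -0.11
  insertion_frame: 1
  bend:
    enabled: no
    a:
    - 0.0
    - 0.0
    - 0.0
    b:
    - 0.0
    - 0.0
    - 0.0
    normal:
    - 0.0
    - 0.0
    - 1.0
    frame: 1
  F_max: 600.0
  tau_act: 0.02
  k_passive: 50.0
  b_passive: 20.0
  v_max: 0.6
- name: internal_rotator
  origin:
  - -0.05
  - 0.07
  - 0.0
  origin_frame: 0
  insertion:
  - 0.04
  - 0.01
  - -0.06
  insertion_frame: 1
  bend:
    enabled: no
    a:
    - 0.0
    - 0.0
    - 0.0
    b:
    - 0.0
    - 0.0
    - 0.0
    normal:
    - 0.0
    - 0.0
    - 1.0
    frame: 1
  F_max: 250.0
  tau_act: 0.02
  k_passive: 50.0
  b_passive: 20.0
  v_max: 0.6
- name: external_rotator
  origin:
  - -0.05
  - -0.07
  - 0.0
  origin_frame: 0
  insertion:
  - 0.04
  - -0.01
  - -0.06
  insertion_frame: 1
  bend:
    enabled: no
    a:
    - 0.0
    - 0.0
    - 0.0
    b:
    - 0.0
    - 0.0
    - 0.0
    normal:
    - 0.0
    - 0.0
    - 1.0
    frame: 1
  F_max: 250.0
  tau_act: 0.02
  k_passive: 50.0
  b_passive: 20.0
  v_max: 0.6
- name: biceps
  origin:
  - 0.0
  - 0.04
  - 0.02
  origin_frame: 0
  insertion:
  - 0.0
  - 0.03
  - -0.335
  insertion_frame: 2
  bend:
    enabled: yes
    a:
    - -0.04
    - 0.05
    - -0.295
    b:
    - 0.04
    - 0.05
    - -0.295
    normal:
    - 0.0
    - 0.0
    - 1.0
    frame: 1
  F_max: 450.0
  tau_act: 0.02
  k_passive: 50.0
  b_passive: 20.0
  v_max: 0.6
- name: triceps
  origin:
  - 0.0
  - -0.05
  - 0.02
  origin_frame: 0
  insertion:
  - 0.0
  - -0.04
  - -0.31
  insertion_frame: 2
  bend:
    enabled: yes
    a:
    - -0.04
    - -0.05
    - -0.29
    b:
    - 0.04
    - -0.05
    - -0.29
    normal:
    - 0.0
    - 0.0
    - 1.0
    frame: 1
  F_max: 450.0
  tau_act: 0.02
  k_passive: 50.0
  b_passive: 20.0
  v_max: 0.6
- name: brachialis
  origin:
  - 0.0
  - 0.035
  - -0.17
  origin_frame: 1
  insertion:
  - 0.0
  - 0.035
  - -0.34
  insertion_frame: 2
  bend:
    enabled: yes
    a:
    - -0.04
    - 0.045
    - -0.3
    b:
    - 0.04
    - 0.045
    - -0.3
    normal:
    - 0.0
    - 0.0
    - 1.0
    frame: 1
  F_max: 400.0
  tau_act: 0.02
  k_passive: 50.0
  b_passive: 20.0
  v_max: 0.6
- name: stabilizer_ant
  origin:
  - 0.06
  - 0.06
  - 0.03
  origin_frame: 0
  insertion:
  - 0.025
  - 0.025
  - -0.09
  insertion_frame: 1
  bend:
    enabled: no
    a:
    - 0.0
    - 0.0
    - 0.0
    b:
    - 0.0
    - 0.0
    - 0.0
    normal:
    - 0.0
    - 0.0
    - 1.0
    frame: 1
  F_max: 300.0
  tau_act: 0.02
  k_passive: 50.0
  b_passive: 20.0
  v_max: 0.6
- name: stabilizer_post
  origin:
  - 0.06
  - -0.06
  - 0.03
  origin_frame: 0
  insertion:
  - 0.025
  - -0.025
  - -0.09
  insertion_frame: 1
  bend:
    enabled: no
    a:
    - 0.0
    - 0.0
    - 0.0
    b:
    - 0.0
    - 0.0
    - 0.0
    normal:
    - 0.0
    - 0.0
    - 1.0
    frame: 1
  F_max: 300.0
  tau_act: 0.02
  k_passive: 50.0
  b_passive: 20.0
  v_max: 0.6
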