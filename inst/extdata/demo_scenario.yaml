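n_donors: 24
age_range:
- 18.0
- 80.0
sex_balance: 0.5
sensitivity_sd: 0.25
shared_sensitivity: yes
design:
  doses:
  - 0.01
  - 0.1
  - 1.0
  - 10.0
  - 50.0
  - 100.0
  replicates: 3
  noise_sd: 5.0
  viability_cap: 120.0
drugs:
- name: albuterol
  clinical_dili: no
  median_log_ic50: 3.4
  donor_sd: 0.4
  hill: 1.0
  plateau_floor: 0.0
  sex_effect: 0.0
  age_slope: 0.0
- name: flavoxate
  clinical_dili: no
  median_log_ic50: 3.5
  donor_sd: 0.4
  hill: 1.0
  plateau_floor: 0.0
  sex_effect: 0.0
  age_slope: 0.0
- name: lenvatinib
  clinical_dili: no
  median_log_ic50: 3.8
  donor_sd: 0.35
  hill: 1.0
  plateau_floor: 0.0
  sex_effect: 0.0
  age_slope: 0.0
- name: beta-estradiol
  clinical_dili: yes
  median_log_ic50: 2.45
  donor_sd: 0.45
  hill: 1.0
  plateau_floor: 0.0
  sex_effect: -0.45
  age_slope: -0.01
- name: etoposide
  clinical_dili: yes
  median_log_ic50: 2.25
  donor_sd: 0.5
  hill: 1.0
  plateau_floor: 0.0
  sex_effect: 0.0
  age_slope: 0.0
- name: nizatidine
  clinical_dili: yes
  median_log_ic50: 2.55
  donor_sd: 0.45
  hill: 1.0
  plateau_floor: 0.0
  sex_effect: 0.0
  age_slope: -0.022
- name: azathioprine
  clinical_dili: yes
  median_log_ic50: 0.7
  donor_sd: 0.5
  hill: 2.0
  plateau_floor: 65.0
  sex_effect: 0.0
  age_slope: 0.0
- name: oxaliplatin
  clinical_dili: yes
  median_log_ic50: 0.5
  donor_sd: 0.3
  hill: 1.0
  plateau_floor: 0.0
  sex_effect: 0.0
  age_slope: -0.008
- name: bosentan
  clinical_dili: yes
  median_log_ic50: 0.6
  donor_sd: 0.3
  hill: 1.0
  plateau_floor: 0.0
  sex_effect: 0.0
  age_slope: 0.0
- name: stavudine
  clinical_dili: yes
  median_log_ic50: 2.6
  donor_sd: 0.5
  hill: 1.0
  plateau_floor: 0.0
  sex_effect: 0.0
  age_slope: 0.0
- name: cabozantinib
  clinical_dili: yes
  median_log_ic50: 0.4
  donor_sd: 0.3
  hill: 1.0
  plateau_floor: 0.0
  sex_effect: 0.0
  age_slope: 0.0
- name: sorafenib
  clinical_dili: yes
  median_log_ic50: 0.55
  donor_sd: 0.35
  hill: 1.0
  plateau_floor: 0.0
  sex_effect: 0.0
  age_slope: 0.0
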