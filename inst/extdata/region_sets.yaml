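# Canonical white-matter region sets for FA event modelling.
# Labels are ASCII tokens; `tract` gives the anatomical name. The three
# corticospinal-tract segments carry MNI z-axis boundaries (z_min/z_max,
# .inf = unbounded). The corpus callosum is never split by hemisphere.
region_sets:
  combined:
    mode: combined
    regions:
      - {label: CST_inf, tract: Corticospinal tract, z_min: -.inf, z_max: -5}
      - {label: CST_mid, tract: Corticospinal tract, z_min: -4, z_max: 18}
      - {label: CST_sup, tract: Corticospinal tract, z_min: 19, z_max: .inf}
      - {label: CC_genu, tract: Corpus callosum}
      - {label: CC_body, tract: Corpus callosum}
      - {label: CC_splenium, tract: Corpus callosum}
      - {label: Cingulum, tract: Cingulum (dorsal section)}
      - {label: SLF, tract: Superior longitudinal fasciculus}
      - {label: ILF, tract: Inferior longitudinal fasciculus}
      - {label: IFOF, tract: Inferior fronto-occipital fasciculus}
      - {label: UF, tract: Uncinate fasciculus}
  split:
    mode: split
    regions:
      - {label: CST_inf_L, tract: Corticospinal tract, hemisphere: L, z_min: -.inf, z_max: -5}
      - {label: CST_inf_R, tract: Corticospinal tract, hemisphere: R, z_min: -.inf, z_max: -5}
      - {label: CST_mid_L, tract: Corticospinal tract, hemisphere: L, z_min: -4, z_max: 18}
      - {label: CST_mid_R, tract: Corticospinal tract, hemisphere: R, z_min: -4, z_max: 18}
      - {label: CST_sup_L, tract: Corticospinal tract, hemisphere: L, z_min: 19, z_max: .inf}
      - {label: CST_sup_R, tract: Corticospinal tract, hemisphere: R, z_min: 19, z_max: .inf}
      - {label: CC_genu, tract: Corpus callosum}
      - {label: CC_body, tract: Corpus callosum}
      - {label: CC_splenium, tract: Corpus callosum}
      - {label: Cingulum_L, tract: Cingulum (dorsal section), hemisphere: L}
      - {label: Cingulum_R, tract: Cingulum (dorsal section), hemisphere: R}
      - {label: SLF_L, tract: Superior longitudinal fasciculus, hemisphere: L}
      - {label: SLF_R, tract: Superior longitudinal fasciculus, hemisphere: R}
      - {label: ILF_L, tract: Inferior longitudinal fasciculus, hemisphere: L}
      - {label: ILF_R, tract: Inferior longitudinal fasciculus, hemisphere: R}
      - {label: IFOF_L, tract: Inferior fronto-occipital fasciculus, hemisphere: L}
      - {label: IFOF_R, tract: Inferior fronto-occipital fasciculus, hemisphere: R}
      - {label: UF_L, tract: Uncinate fasciculus, hemisphere: L}
      - {label: UF_R, tract: Uncinate fasciculus, hemisphere: R}
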