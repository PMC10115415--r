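species:
- C
- C_K83A
- C_KRK
- C_RK
- C_WLF
- CM
- CMda
- H
- M
- PHD3
- R
kon_default: 10.0
constants:
- pair:
  - M
  - H
  kd_uM: 4.0
  censored: no
  source: ITC, MLL1 PHD3-BRD reader + H3K4me3 peptide
- pair:
  - PHD3
  - H
  kd_uM: 51.0
  censored: no
  source: ITC, isolated MLL1 PHD3 + H3K4me3 peptide
- pair:
  - C
  - M
  kd_uM: 4.6
  censored: no
  source: ITC, Cyp33 RRM + MLL1 PHD3
- pair:
  - CM
  - H
  kd_uM: 70.0
  censored: no
  source: ITC, Cyp33 RRM:PHD3 complex + H3K4me3
- pair:
  - CMda
  - H
  kd_uM: 24.0
  censored: no
  source: ITC, Cyp33 RRM(delta-alpha3):PHD3 complex + H3K4me3
- pair:
  - C
  - R
  kd_uM: 300.0
  censored: no
  source: NMR titration, Cyp33 WT + UAAUGU RNA
- pair:
  - C_WLF
  - R
  kd_uM: 70.0
  censored: no
  source: NMR titration + ITC, Cyp33 W101A/L102A/F105A + UAAUGU
- pair:
  - C_K83A
  - R
  kd_uM: 1800.0
  censored: no
  source: NMR titration, Cyp33 K83A + UAAUGU
- pair:
  - C_RK
  - R
  kd_uM: 2000.0
  censored: no
  source: NMR titration, Cyp33 R86A/K88A + UAAUGU
- pair:
  - C_KRK
  - R
  kd_uM: 10000.0
  censored: yes
  source: NMR titration, Cyp33 K83A/R86A/K88A + UAAUGU; lower bound
- pair:
  - R
  - H
  kd_uM: 30.0
  censored: no
  source: ITC, repeat RNA + H3K4me3 peptide
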