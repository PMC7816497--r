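# Frozen default baseline cause-specific hazards (per month) over the
# intervals starting at months 0, 12, 36, 60, 96.  Obtained once by a
# deterministic least-squares calibration of the generator's pooled OS/CSS
# at 1/3/5/8 years and the cancer-specific share of deaths against the
# reference cohort values (see the methods vignette); the last interval's
# rate carries a late-hazard upturn.
calibrated_baseline_hazards <- list(
  cancer = c(0.00139356, 0.00161679, 0.00134448, 0.00121161, 0.00181742),
  other  = c(0.000316966, 0.000365915, 0.000316013, 0.000479838, 0.000719756)
)
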