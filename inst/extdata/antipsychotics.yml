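# Antipsychotic gazetteer with maximum recommended daily doses (mg).
# Maxima follow standard UK prescribing references for adult oral use; this
# table is deliberately small, editable configuration, not a reproduction of
# any formulary. strengths_mg lists common tablet strengths and is used by
# the synthetic-note generator to place doses on a plausible grid.
drugs:
  - generic: olanzapine
    synonyms: [zyprexa]
    max_daily_mg: 20
    strengths_mg: [2.5, 5, 10, 15, 20]
  - generic: risperidone
    synonyms: [risperdal]
    max_daily_mg: 16
    strengths_mg: [0.5, 1, 2, 3, 4, 6]
  - generic: haloperidol
    synonyms: [haldol, serenace]
    max_daily_mg: 20
    strengths_mg: [0.5, 1.5, 5, 10]
  - generic: quetiapine
    synonyms: [seroquel]
    max_daily_mg: 750
    strengths_mg: [25, 100, 150, 200, 300]
  - generic: aripiprazole
    synonyms: [abilify]
    max_daily_mg: 30
    strengths_mg: [5, 10, 15, 30]
  - generic: clozapine
    synonyms: [clozaril, zaponex]
    max_daily_mg: 900
    strengths_mg: [25, 50, 100, 200]
  - generic: amisulpride
    synonyms: [solian]
    max_daily_mg: 1200
    strengths_mg: [50, 100, 200, 400]
  - generic: chlorpromazine
    synonyms: [largactil]
    max_daily_mg: 1000
    strengths_mg: [25, 50, 100]
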