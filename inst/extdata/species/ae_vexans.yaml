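# Aedes vexans -- floodwater mosquito, overwinters as eggs.
# Development times follow d = A * T^-a of the 10-day mean temperature;
# exponents are literature values, the A coefficients are package
# defaults scaled so that embryogenesis ~3 d and larva/pupa ~8 d at 25 C
# (a full generation takes under 3 weeks in favourable conditions).
name: Ae.vexans
development:
  embryo:
    A: 1360.0      # 3 d at 25 C
    a: 1.90
  larva:
    A: 3188.0      # 8 d at 25 C
    a: 1.86
  stage_time_sd: 1.0
  temp_floor: 1.0  # clamp T before the power law (diverges at 0 C)
gonotrophic:
  type: truncnorm
  mean: 10.0
  sd: 1.0
  lower: 7.0
  upper: 13.0
survival:            # daily rates
  egg:
    type: constant
    value: 0.998   # diapausing floodwater eggs are highly durable
  larva:             # quadratic in 10-day mean T: peak - ((T-opt)/width)^2
    type: quadratic
    opt: 26.0
    peak: 0.97
    width: 35.0
  adult:
    type: quadratic
    opt: 24.0
    peak: 0.92
    width: 28.0
  dry_penalty: 0.97  # multiplies larva/adult survival when p10 < 1 mm/day
  dd_egg_slope: 1.0e-6    # per-capita linear density dependence
  dd_larva_slope: 2.0e-6
bloodmeal:           # oviposition success prob, linear in 10-day mean RH
  type: linear_rh
  b0: 0.0
  b1: 0.009
eggs:                # eggs per batch ~ Normal(base + slope*precip, sd)
  base_mean: 100.0
  precip_slope: 5.0
  sd: 20.0
female_fraction: 0.5
overwinter_stage: egg
diapause_temp: 12.0        # 10-day mean T below which the overwintering
                           # stage's development clock freezes
hatch_rain_threshold: 5.0  # mm/day needed to inundate and hatch eggs
                           # (ignored when rainfall effects are off)
hatch_temp: 15.0           # minimum 10-day mean T for hatching
hatch_fraction: 0.5        # fraction of the ready egg bank hatching per
                           # inundation event (installment hatching)
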