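# Culiseta melanura -- crypt breeder, exceptionally slow larval
# development, cold tolerant, overwinters in larval stages.
# The embryogenesis exponent is the printed literature value 0.30; if
# it is read as a truncation of 2.30, swap the alternative block below.
name: Cs.melanura
development:
  embryo:
    A: 14.3        # ~6 d at 18 C with a = 0.30
    a: 0.30
    # alternative reading: {A: 4600.0, a: 2.30} gives ~6 d at 18 C too
  larva:
    A: 90000.0     # ~135 d at 18 C, ~64 d at 25 C: exceptionally low
                   # development rate; immatures take months in crypts
    a: 2.25
  stage_time_sd: 1.0
  temp_floor: 1.0
gonotrophic:         # mean decreases with temperature, unit sd
  type: norm_temp
  intercept: 28.0    # mean = max(floor_mean, intercept - slope * t10)
  slope: 0.9         # ~11.8 d at 18 C, ~5.5 d at 25 C
  sd: 1.0
  floor_mean: 4.0
  floor: 1.0         # draws floored at 1 day
survival:
  egg:
    type: constant
    value: 0.995
  larva:             # baseline 1 under zero crowding and wet conditions;
    type: constant   # reduced only by density dependence and dryness
    value: 1.0
  adult:             # cold-tolerant: flatter curve, cooler optimum and
    type: quadratic  # longer adult life than Ae.vexans
    opt: 20.0
    peak: 0.97
    width: 30.0
  dry_penalty: 0.99  # crypt habitats buffer larvae against dry spells
  dd_egg_slope: 1.0e-6
  dd_larva_slope: 2.0e-6
bloodmeal:           # increasing quadratic in 10-day mean temperature
  type: quad_temp
  q0: 0.03
  q2: 0.0011
eggs:
  base_mean: 100.0
  precip_slope: 5.0
  sd: 20.0
female_fraction: 0.5
overwinter_stage: larva
diapause_temp: 10.0
hatch_rain_threshold: 0.0   # not a floodwater species: eggs hatch on
                            # completing embryogenesis
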