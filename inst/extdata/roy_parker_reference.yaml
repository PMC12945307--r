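# Reference (population) values for the modified Roy-Parker glucose-insulin
# model with exercise, used as the centre of the admissible parameter box
# [0.2 * xref, 1.8 * xref].  Values follow the Roy & Parker exercise minimal
# model literature; override per patient as needed.
#
# version: 1
"n": 0.09259    # 1/min    plasma insulin clearance rate (5/54)
VolG: 117.0     # dl       glucose distribution volume
p1: 0.035       # 1/min    glucose effectiveness (return to basal)
p2: 0.05        # 1/min    remote insulin clearance
p3: 2.8e-05     # ml/(uU min^2)  remote insulin appearance
p4: 0.08333     # (uU/ml)/(mU)   plasma insulin appearance per infused mU (1/12)
a1: 0.00158     # mg/kg/min per PVO2max   exercise-induced hepatic production
a2: 0.056       # 1/min    decay of exercise-induced production
a3: 0.00195    # mg/kg/min per PVO2max   exercise-induced glucose uptake
a4: 0.0485      # 1/min    decay of exercise-induced uptake
a5: 0.00125     # uU/ml/min per PVO2max  exercise-induced insulin removal
a6: 0.075       # 1/min    decay of exercise-induced insulin removal
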