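# Patient profile for the worked example: a type 1 insulin user who reports
# an insulin sensitivity factor, an insulin-to-carbohydrate ratio and a
# carbohydrate absorption rate.
diabetes_type: 1
uses_insulin: true
reported_isf: 2.5        # mmol/L per U
reported_icr: 10         # g per U
carb_absorption_rate: 30 # g per hour
low_carb_diet: false
dia: 4                   # insulin action duration, hours
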