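timestamp,data_type,value,unit,activity_kind,activity_tag,factor_tag,source,manual
2024-03-04 07:10,blood_glucose,5.4,mmol/L,,,,meter,TRUE
2024-03-04 08:00,carbohydrates,40,g,,,,diary_app,TRUE
2024-03-04 08:00,insulin_bolus,4,U,,,,pen,TRUE
2024-03-04 10:30,blood_glucose,120,mg/dL,,,,meter_us,TRUE
2024-03-04 12:00,carbohydrates,85,g,,,,diary_app,TRUE
2024-03-04 12:00,insulin_bolus,6,U,,,,pen,TRUE
2024-03-04 14:00,blood_glucose,15.0,mmol/L,,,,meter,TRUE
2024-03-04 16:00,physical_activity,30,,minutes,,,diary_app,TRUE
2024-03-04 18:00,carbohydrates,55,g,,,,diary_app,TRUE
2024-03-04 18:00,insulin_bolus,5.5,U,,,,pen,TRUE
2024-03-04 19:30,blood_glucose,6.2,mmol/L,,,,meter,TRUE
2024-03-04 21:30,blood_glucose,5.8,mmol/L,,,,meter,TRUE
2024-03-04 22:00,insulin_basal,20,U,,,,pen,TRUE
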