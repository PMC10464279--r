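column	type	required	description
subject_id	character	yes	unique subject identifier, matched against methylation sample ids
bedtime_weekday	hh:mm or decimal hours	if bedtime_sr absent	self-reported weekday bedtime (questionnaire item)
bedtime_weekend	hh:mm or decimal hours	if bedtime_sr absent	self-reported weekend bedtime (questionnaire item)
bedtime_sr	hh:mm or decimal hours	alternative to the two raw items	precomputed weighted self-report bedtime (5:2 weekday/weekend)
bedtime_act	hh:mm or decimal hours	yes	actigraphy average bedtime
bedtime_psg	hh:mm or decimal hours	yes	polysomnography lights-out time
sol_sr	minutes	yes	self-reported sleep onset latency
sol_act	minutes	yes	actigraphy sleep onset latency
sol_psg	minutes	yes	polysomnography sleep onset latency (lights-out to first stage-2 epoch)
sot_sr	hh:mm or decimal hours	no	self-report sleep onset time; derived as bedtime + sol/60 when absent, re-checked to 1 minute when present
sot_act	hh:mm or decimal hours	no	actigraphy sleep onset time (same rule)
sot_psg	hh:mm or decimal hours	no	polysomnography sleep onset time (same rule)
age	years	yes	adjustment covariate
sex	0/1 (1 = male)	yes	adjustment covariate
race	0/1 (1 = non-minority)	yes	adjustment covariate
bmi_percentile	0-100	yes	adjustment covariate, continuous
batch	label	yes	assay batch, one-hot coded with the first batch as reference
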