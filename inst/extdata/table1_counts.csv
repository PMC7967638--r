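variable,category,reference,n_total,n_events
marital_status,married,TRUE,423,2
marital_status,unmarried,FALSE,27,2
marital_status,not_answered,FALSE,26,1
marital_status,not_investigated,FALSE,417,6
maternal_age,<20,FALSE,13,1
maternal_age,20-24,FALSE,94,3
maternal_age,25-39,TRUE,753,6
maternal_age,>=40,FALSE,33,1
late_registration,no,TRUE,812,9
late_registration,yes,FALSE,55,2
late_registration,not_answered,FALSE,26,0
pregnancy_progress,good/not_answered,TRUE,557,8
pregnancy_progress,not_good,FALSE,10,0
pregnancy_progress,not_investigated,FALSE,326,3
birth_order,subsequent/not_answered,TRUE,495,7
birth_order,first,FALSE,398,4
abortion_history,no/not_answered,TRUE,834,7
abortion_history,yes,FALSE,59,4
infertility_treatment,no,TRUE,696,10
infertility_treatment,yes,FALSE,67,0
infertility_treatment,not_answered,FALSE,6,0
infertility_treatment,not_investigated,FALSE,124,1
feeling_at_pregnancy,happy,TRUE,647,7
feeling_at_pregnancy,unexpected_happy,FALSE,185,2
feeling_at_pregnancy,unexpected_other,FALSE,54,1
feeling_at_pregnancy,not_answered,FALSE,7,1
return_to_parents_home,yes,TRUE,317,2
return_to_parents_home,no,FALSE,440,8
return_to_parents_home,not_answered,FALSE,12,0
return_to_parents_home,not_investigated,FALSE,124,1
has_helper,yes,TRUE,870,9
has_helper,no,FALSE,13,1
has_helper,not_answered,FALSE,10,1
worries_anxiety,no,TRUE,418,4
worries_anxiety,yes,FALSE,264,5
worries_anxiety,not_answered,FALSE,9,0
worries_anxiety,not_investigated,FALSE,202,2
smoking,no/not_answered,TRUE,776,6
smoking,stopped_after_confirmation,FALSE,94,3
smoking,yes,FALSE,23,2
passive_smoking,no/not_answered,TRUE,481,5
passive_smoking,yes,FALSE,86,3
passive_smoking,not_investigated,FALSE,326,3
alcohol,no,TRUE,874,10
alcohol,yes,FALSE,8,1
alcohol,not_answered,FALSE,11,0
disease_history,no/not_answered,TRUE,476,6
disease_history,yes,FALSE,91,2
disease_history,not_investigated,FALSE,326,3
mental_illness_history,no,TRUE,310,3
mental_illness_history,yes,FALSE,25,1
mental_illness_history,not_answered,FALSE,434,6
mental_illness_history,not_investigated,FALSE,124,1
depressive_symptoms,no,TRUE,820,9
depressive_symptoms,yes,FALSE,66,2
depressive_symptoms,not_answered,FALSE,7,0
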