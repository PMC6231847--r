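record_id,same_day,complete,valid,clause
r01,TRUE,TRUE,TRUE,clean same-day follow-up
r02,TRUE,FALSE,TRUE,visit reason is the catch-all 'other'
r03,TRUE,FALSE,TRUE,initial encounter missing referral source
r04,TRUE,FALSE,TRUE,initial encounter with unknown-referral sentinel; 6-month rule skipped
r05,TRUE,TRUE,TRUE,complete initial encounter
r06,FALSE,TRUE,TRUE,entered one day after appointment
r07,FALSE,TRUE,FALSE,appointment after entry date
r08,TRUE,TRUE,FALSE,appointment exactly on 2008-01-01 (rule is strictly after)
r09,FALSE,TRUE,TRUE,entry one day under the 4-calendar-month limit
r10,FALSE,TRUE,FALSE,entry exactly at 4 calendar months (rule is strictly under)
r11,TRUE,TRUE,TRUE,referral-to-appointment gap exactly 6 calendar months (allowed)
r12,TRUE,TRUE,FALSE,referral-to-appointment gap one day over 6 calendar months
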