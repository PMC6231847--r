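record_id,user_id,profession,encounter_type,appointment_date,entry_date,referral_date,referral_source,visit_reason,no_show
r01,u1,nurse,follow_up,2016-11-01,2016-11-01,,,counseling,false
r02,u1,nurse,follow_up,2016-11-01,2016-11-01,,,other,false
r03,u1,nurse,initial,2016-11-01,2016-11-01,2016-10-01,,counseling,false
r04,u1,nurse,initial,2016-11-01,2016-11-01,1900-01-01,family_physician,counseling,false
r05,u1,nurse,initial,2016-11-01,2016-11-01,2016-10-01,family_physician,counseling,false
r06,u1,nurse,follow_up,2016-11-01,2016-11-02,,,counseling,false
r07,u1,nurse,follow_up,2016-11-02,2016-11-01,,,counseling,true
r08,u1,nurse,follow_up,2008-01-01,2008-01-01,,,counseling,false
r09,u1,nurse,follow_up,2016-06-01,2016-09-30,,,counseling,false
r10,u1,nurse,follow_up,2016-06-01,2016-10-01,,,counseling,false
r11,u1,nurse,initial,2016-07-15,2016-07-15,2016-01-15,family_physician,counseling,false
r12,u1,nurse,initial,2016-07-16,2016-07-16,2016-01-15,family_physician,counseling,false
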