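profile,current_age,smoking,bmi,oc_use_years,age_first_birth,parity,menopause_status,age_at_menopause,mht_use_years,ep_mht_use_years,other_mht_use,family_history_breast_ovarian,benign_breast_disease,alcohol_drinks_per_day
1,50,never,24,0,25,3,premenopausal,NA,0,0,FALSE,FALSE,FALSE,0
2,50,never,21,0,24,4,premenopausal,NA,0,0,FALSE,FALSE,FALSE,0
3,50,current,24,0,21,3,premenopausal,NA,0,0,FALSE,FALSE,FALSE,0.5
4,50,current,25,0,22,3,premenopausal,NA,0,0,TRUE,FALSE,TRUE,0.5
5,50,former,30,10,37,1,postmenopausal,50,1,1,FALSE,TRUE,TRUE,1
6,50,former,35,10,41,1,postmenopausal,50,1,1,FALSE,TRUE,TRUE,1
7,50,never,40,10,39,1,postmenopausal,50,1,1,FALSE,TRUE,FALSE,1
8,50,never,35,10,NA,0,premenopausal,NA,11,11,FALSE,FALSE,FALSE,1
9,65,never,24,0,25,3,postmenopausal,49,0,0,FALSE,FALSE,FALSE,0
10,65,former,21,0,24,4,postmenopausal,47,3,3,FALSE,FALSE,FALSE,0
11,65,former,24,0,21,3,postmenopausal,49,5,5,FALSE,FALSE,FALSE,0.5
12,65,current,25,0,22,3,postmenopausal,48,5,5,FALSE,FALSE,TRUE,0.5
13,65,current,30,10,37,1,postmenopausal,55,10,10,FALSE,TRUE,TRUE,1
14,65,former,35,10,41,1,postmenopausal,57,11,11,FALSE,TRUE,TRUE,1
15,65,never,40,10,39,1,postmenopausal,56,12,12,FALSE,TRUE,FALSE,1
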