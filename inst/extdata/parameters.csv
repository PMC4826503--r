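"name","mean","sd","distribution","hyper_a","hyper_b","group","role"
"cost_pre_transplant_visit",569,0,"fixed",NA,NA,"costs","one-time assessment visit before the first transplantation"
"cost_transplant_procedure",91414,13712,"lognormal",11.412029,0.149166,"costs","transplantation incl. initial medication, 4-day stay"
"cost_tacrolimus_month",450,33.75,"lognormal",6.106443,0.074895,"costs","tacrolimus per month (component of per-cycle immunosuppression)"
"cost_mmf_month",500,37.5,"lognormal",6.211803,0.074895,"costs","mycophenolate mofetil per month (component)"
"cost_alemtuzumab",0,0,"fixed",NA,NA,"costs","induction agent, provided at no charge (compassionate release)"
"cost_basiliximab",3000,0,"fixed",NA,NA,"costs","once at 2nd transplant for about half of patients"
"cost_valganciclovir_course",5000,375,"lognormal",8.514389,0.074895,"costs","14-week antiviral prophylaxis course"
"cost_anakinra_course",574,43,"lognormal",6.349825,0.074895,"costs","anakinra for the 3 days after discharge"
"cost_immunosuppression_cycle",713.5,53.5,"lognormal",6.56667,0.074895,"costs","branded tacrolimus + MMF per 1/16-year cycle"
"cost_immunosuppression_generic_cycle",238.1,17.9,"lognormal",5.46808,0.074895,"costs","generic immunosuppression per cycle (1/3 of branded)"
"cost_followup_visit",556,42,"lognormal",6.318,0.074895,"costs","post-transplant check-up visit (annual after year 1)"
"cost_iit_cycle",159,12,"lognormal",5.0692,0.074895,"costs","intensive insulin therapy without complications, per cycle"
"cost_drc_cycle",602,120,"gamma",25,24.0796,"costs","IIT with diabetes-related complications, per cycle"
"cost_initial_complication",600,180,"gamma",11.1111,54,"costs","extra cost of initial transplant/immunosuppressive complications"
"cost_major_complication",6500,1300,"gamma",25,260,"costs","extra cost per major immunosuppressive complication"
"u_full_graft",0.82,0.04,"beta",70.56,15.48,"effectiveness_safety","annual utility, full graft function (insulin independent)"
"du_partial_graft",0.01,0.002,"gamma",25,4e-04,"effectiveness_safety","decrement full -> partial graft function"
"du_iit",0.1,0.02,"gamma",25,0.004,"effectiveness_safety","decrement partial graft -> IIT with hypoglycemia unawareness"
"du_drc",0.14,0.042,"gamma",11.11,0.0126,"effectiveness_safety","decrement IIT -> IIT with diabetes-related complications"
"du_initial_complication",0.05,0.01,"gamma",25,0.002,"effectiveness_safety","one-time disutility per initial complication"
"du_major_complication",0.1,0.025,"gamma",16,0.00625,"effectiveness_safety","one-time disutility per major immunosuppressive complication"
"ratio_initial_complications",0.65,0.065,"beta",34.3,18.47,"effectiveness_safety","share of patients with initial complications per transplantation"
"p_full_tx1",0.15,0.0375,"beta",13.45,76.21,"effectiveness_safety","insulin independent 23 days after 1st transplantation"
"p_full_tx2",0.7,0.105,"beta",12.63,5.41,"effectiveness_safety","insulin independent 23 days after 2nd transplantation"
"p_full_tx34",0.85,0.1275,"beta",5.8,1.02,"effectiveness_safety","insulin independent 23 days after 3rd/4th transplantation"
"hr_drc_partial",0.45,0.0675,"lognormal",-0.8096,0.149166,"effectiveness_safety","hazard ratio of diabetes-related complications, partial graft"
"ratio_hr_drc_full",0.5556,0.084,"lognormal",-0.59891,0.149166,"effectiveness_safety","nested ratio: full-graft DRC HR as share of partial-graft HR (-> 0.25)"
"p_full_to_partial",0.0077379,0.001161,"beta",44.09,5653.02,"effectiveness_safety","full -> partial graft function, per cycle"
"p_full_graft_failure",1.64732e-05,2.47e-06,"beta",44.44,2697667,"effectiveness_safety","full graft -> graft failure, per cycle"
"p_partial_failure_first6m",0.045,0.00675,"beta",42.4,899.81,"effectiveness_safety","partial graft failure within first 6 months, per cycle"
"p_partial_failure_after6m",0.00532,0.000798,"beta",44.2,8264,"effectiveness_safety","partial graft failure after first 6 months, per cycle"
"p_major_complication",6.201e-05,9.302e-06,"beta",44.44,716613,"effectiveness_safety","major immunosuppressive complication in graft states, per cycle"
"ratio_stop_immunosuppression",0.1,0.015,"beta",39.9,359.1,"effectiveness_safety","share of major complications forcing immunosuppression stop"
"p_drc_base",0.0018185,0.000364,"beta",24.96,13700.6,"natural_history","diabetes-related complications without graft protection, per cycle"
"hr_mortality_hypoglycemia",2.4,0.24,"lognormal",0.870494,0.099751,"natural_history","mortality hazard ratio, hypoglycemia unawareness (IIT states)"
"ratio_hr_mortality_drc",2.9845,0.29845,"lognormal",1.088457,0.099751,"natural_history","nested ratio: DRC mortality HR as multiple of hypoglycemia HR (-> 7.16)"
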