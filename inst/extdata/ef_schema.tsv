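variable	test	domain	polarity	kind
tmt_a_time	TMT	cognitive_flexibility	lower_better	speed
tmt_b_time	TMT	cognitive_flexibility	lower_better	speed
tmt_b_minus_a	TMT	cognitive_flexibility	lower_better	main
tmt_errors	TMT	cognitive_flexibility	lower_better	main
spm_correct	SPM	cognitive_flexibility	higher_better	main
spm_time	SPM	cognitive_flexibility	lower_better	speed
spm_errors	SPM	cognitive_flexibility	lower_better	main
wcst_correct	WCST	cognitive_flexibility	higher_better	main
wcst_persev_errors	WCST	cognitive_flexibility	lower_better	main
wcst_nonpersev_errors	WCST	cognitive_flexibility	lower_better	main
wcst_categories	WCST	cognitive_flexibility	higher_better	main
wcst_trials_first_cat	WCST	cognitive_flexibility	lower_better	main
wcst_failures_to_maintain	WCST	cognitive_flexibility	lower_better	main
wcst_mean_rt	WCST	cognitive_flexibility	lower_better	speed
tol_correct	TOL	cognitive_flexibility	higher_better	main
tol_planning_time	TOL	cognitive_flexibility	lower_better	speed
tol_execution_time	TOL	cognitive_flexibility	lower_better	speed
tol_moves	TOL	cognitive_flexibility	lower_better	main
tol_rule_breaks	TOL	cognitive_flexibility	lower_better	main
switch_cost_rt	SWITCH	cognitive_flexibility	lower_better	main
switch_cost_errors	SWITCH	cognitive_flexibility	lower_better	main
switch_repeat_rt	SWITCH	cognitive_flexibility	lower_better	speed
switch_repeat_errors	SWITCH	cognitive_flexibility	lower_better	main
switch_mixing_cost	SWITCH	cognitive_flexibility	lower_better	main
switch_mean_rt	SWITCH	cognitive_flexibility	lower_better	speed
nbn_errors	NBN	working_memory	lower_better	main
nbn_hits	NBN	working_memory	higher_better	main
nbn_false_alarms	NBN	working_memory	lower_better	main
nbn_mean_rt	NBN	working_memory	lower_better	speed
nbn_dprime	NBN	working_memory	higher_better	main
nvlt_correct	NVLT	working_memory	higher_better	main
nvlt_errors	NVLT	working_memory	lower_better	main
nvlt_diff_correct_errors	NVLT	working_memory	higher_better	main
nvlt_mean_rt	NVLT	working_memory	lower_better	speed
corsi_span_forward	CORSI	working_memory	higher_better	main
corsi_span_backward	CORSI	working_memory	higher_better	main
corsi_total_correct	CORSI	working_memory	higher_better	main
corsi_mean_rt	CORSI	working_memory	lower_better	speed
stop_ssrt	STOP	inhibition	lower_better	main
stop_go_rt	STOP	inhibition	lower_better	speed
stop_accuracy	STOP	inhibition	higher_better	main
stop_omissions	STOP	inhibition	lower_better	main
stop_mean_ssd	STOP	inhibition	higher_better	main
simon_effect_rt	SIMON	inhibition	lower_better	main
simon_effect_errors	SIMON	inhibition	lower_better	main
simon_congruent_rt	SIMON	inhibition	lower_better	speed
simon_incongruent_rt	SIMON	inhibition	lower_better	speed
simon_errors	SIMON	inhibition	lower_better	main
stroop_naming_interference	STROOP	inhibition	lower_better	main
stroop_reading_interference	STROOP	inhibition	lower_better	main
stroop_baseline_rt	STROOP	inhibition	lower_better	speed
stroop_color_rt	STROOP	inhibition	lower_better	speed
stroop_errors	STROOP	inhibition	lower_better	main
stroop_time	STROOP	inhibition	lower_better	speed
wafg_rt_visual	WAF_G	attention	lower_better	speed
wafg_rt_auditory	WAF_G	attention	lower_better	speed
wafg_rt_crossmodal	WAF_G	attention	lower_better	speed
wafg_omissions	WAF_G	attention	lower_better	main
wafg_false_alarms	WAF_G	attention	lower_better	main
wafg_rt_sd	WAF_G	attention	lower_better	main
wafr_rt_correct	WAF_R	attention	lower_better	speed
wafr_rt_announced	WAF_R	attention	lower_better	speed
wafr_omissions	WAF_R	attention	lower_better	main
wafr_false_alarms	WAF_R	attention	lower_better	main
wafr_rt_sd	WAF_R	attention	lower_better	main
clock_missed	CLOCK	vigilance	lower_better	main
clock_false_alarms	CLOCK	vigilance	lower_better	main
clock_mean_rt	CLOCK	vigilance	lower_better	speed
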