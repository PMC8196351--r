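quantity,value
total_alarms,297830
observation_days,93
beds,21
yellow_alarms_per_day_mean,120.3
red_alarms_per_day_mean,27.5
blue_alarms_per_day_mean,4.6
alarms_per_bed_day_mean,152.5
flood_conditions_total,6468
flood_size_10_20,5289
flood_size_20_40,1012
flood_size_40_100,159
technical_alarms_total,10846
pauses_total,16002
pauses_not_actively_terminated,14719
ecg_rr_alarms,10821
ecg_alarms_total,67518
ventilator_rr_alarms,31911
single_alarms_per_bed_day,172.9
double_alarms_per_bed_day,137.2
single_red_per_bed,2972.9
double_red_per_bed,2250.3
single_yellow_per_bed,12638.8
double_yellow_per_bed,10105.2
beds_above_daily_average_mean,7.6
daily_alarms_from_beds_above_mean,2199.9
daily_alarms_total_mean,3202.4
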