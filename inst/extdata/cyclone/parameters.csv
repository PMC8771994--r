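"parameter","value"
"depot","Province A"
"start_time","08:00"
"return_time","18:00"
"weight_time","5"
"time_budget_seconds","120"
"service_hours_per_stop","0.25"
"fuel_price","1.45"
"per_diem_rate","30"
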