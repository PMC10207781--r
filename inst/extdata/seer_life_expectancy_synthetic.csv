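# SYNTHETIC life-expectancy table (SEER-like shape, not SEER data).
# Life expectancy in years within the 3-year analysis horizon, per
# metastatic stratum. The two values are free pipeline parameters,
# solved once so that the reference life-years-gained totals of the
# packaged configuration equal 47.8 (22-month) and 103.8 (16-month).
# Replace with registry-derived values for a real analysis.
stratum,life_expectancy_years
metastatic,1.2031639
non_metastatic,2.6169570
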