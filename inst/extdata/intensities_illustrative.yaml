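# Illustrative sectoral CO2 emission intensities — NOT agency (MPCA) values.
# The published per-unit rates are not reproduced here; these synthetic
# stand-ins are scaled so that study-area demographic totals yield sectoral
# emissions of realistic magnitude. Replace with agency data for real use.
I_e: 2.0            # lbs CO2 per kWh consumed
E_kwh_per_capita: 25000   # kWh per person per year
I_t: 10.5           # short tons CO2 per vehicle per year
I_a: 50000          # lbs CO2 per acre harvested
I_i: 600            # lbs CO2 per industrial employee
I_c: 30             # lbs CO2 per commercial employee
I_r: 9250           # lbs CO2 per capita (residential)
I_w: 517            # lbs CO2 per capita (wastewater treatment)
nonrenewable_share: 0.70  # fraction of electricity from nonrenewable sources
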