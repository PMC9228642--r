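formulation_id,medium,dt_min,source
IBU,water,NA,not_determined
IBU,HCl_pH1.2,NA,not_determined
IP,water,67.90,printed
IP,HCl_pH1.2,94.56,printed
IP5E,water,57.13,printed
IP5E,HCl_pH1.2,77.13,printed
IP10E,water,47.93,synthetic_interpolated
IP10E,HCl_pH1.2,67.70,synthetic_interpolated
IP20E,water,29.54,synthetic_interpolated
IP20E,HCl_pH1.2,48.85,synthetic_interpolated
IP25E,water,20.35,synthetic_interpolated
IP25E,HCl_pH1.2,39.43,synthetic_interpolated
IP30E,water,11.15,printed
IP30E,HCl_pH1.2,30.00,printed_approximate
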