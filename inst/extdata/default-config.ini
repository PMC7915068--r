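# Wearable gait monitor: physical model configuration.
# Units: magnetic fields in Gauss, lengths in cm, sensitivity in mV/G,
# voltages in V.

[magnet]
# N52 neodymium ring, 1 inch OD, 5/16 inch ID, 1/8 inch thick.
Br = 14800
Ro = 1.27
Ri = 0.397
T = 0.3175

[sensor]
# Ratiometric linear Hall-effect sensor, 10-bit ADC on a 5 V supply.
S = 1.45
Vdd = 5
adc_bits = 10
baseline_code = 512

[mount]
# Sensor package plus circuit board width added to the leg gap.
W_sensor_board = 0.28
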