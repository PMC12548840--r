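# Trap-bar (hexagonal) deadlift (TBDL): flexion range 35-90 deg, first peak 640 N.m
action_id: TBDL
flexion_start_deg: 35
flexion_end_deg: 90
first_peak_torque_Nm: 640
second_peak_torque_Nm: 544
peak_time_fractions: [0.34, 0.78]
trial_duration_s: 2
barbell_mass_kg: 120
noise_sd_mm: 0.5
seed: 0
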