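# Conventional deadlift (DL): flexion range 32-90 deg, first peak torque 749 N.m
action_id: DL
flexion_start_deg: 32
flexion_end_deg: 90
first_peak_torque_Nm: 749
second_peak_torque_Nm: 636.65
peak_time_fractions: [0.32, 0.78]
trial_duration_s: 2
barbell_mass_kg: 120
noise_sd_mm: 0.5
seed: 0
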